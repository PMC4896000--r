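test_that("features match the brute-force per-pixel oracle on random cells", {
  set.seed(21)
  for (i in 1:8) {
    im <- make_disk_image(cell_r = sample(13:20, 1),
                          nuc_r = sample(5:9, 1),
                          c_nuc = runif(1, 10, 40),
                          c_cyto = runif(1, 10, 40),
                          noise_sd = runif(1, 0.5, 2))
    m <- compute_masks(im)
    fe <- extract_features(im, m)
    or <- oracle_features(im, m)
    for (f in names(or))
      expect_equal(fe[[f]], or[[f]], tolerance = 1e-10, label = f)
  }
})

test_that("intensities are additive when the background is zero", {
  im <- make_disk_image(background = 0, noise_sd = 0)
  m <- compute_masks(im)
  fe <- extract_features(im, m)
  expect_equal(fe$intensity_cell,
               fe$intensity_nucleus + fe$intensity_cytoplasm,
               tolerance = 1e-12)
  # concentrations are intensity/area for each compartment
  expect_equal(fe$concentration_nucleus,
               fe$intensity_nucleus / fe$area_nucleus)
  expect_equal(fe$concentration_cytoplasm,
               fe$intensity_cytoplasm / fe$area_cytoplasm)
})

test_that("uniform TFEB signal gives unit ratio and area-proportional share", {
  im <- make_disk_image(c_nuc = 25, c_cyto = 25, background = 0,
                        noise_sd = 0)
  m <- compute_masks(im)
  fe <- extract_features(im, m)
  expect_equal(fe$mean_pixel_nuc_cyto, 1.0, tolerance = 1e-12)
  expect_equal(fe$nuclear_percentage,
               100 * fe$area_nucleus / fe$area_cell, tolerance = 1e-12)
})

test_that("fully nuclear signal gives 100% nuclear percentage", {
  im <- make_disk_image(c_nuc = 40, c_cyto = 0, background = 0,
                        noise_sd = 0)
  m <- compute_masks(im)
  fe <- extract_features(im, m)
  expect_equal(fe$nuclear_percentage, 100)
})

test_that("features are scale-equivariant at zero background", {
  im <- make_disk_image(background = 0, noise_sd = 0)
  m <- compute_masks(im)
  fe1 <- extract_features(im, m)
  im2 <- im
  im2$channels$tfeb <- im$channels$tfeb * 3
  fe2 <- extract_features(im2, compute_masks(im2))
  expect_equal(fe2$intensity_cell, 3 * fe1$intensity_cell)
  expect_equal(fe2$concentration_cell, 3 * fe1$concentration_cell)
  expect_equal(fe2$mean_pixel_nuc_cyto, fe1$mean_pixel_nuc_cyto)
  expect_equal(fe2$nuclear_percentage, fe1$nuclear_percentage)
})

test_that("features are invariant under integer translation", {
  im <- make_disk_image(size = 72, center = c(30, 30), noise_sd = 0)
  im2 <- make_disk_image(size = 72, center = c(40, 38), noise_sd = 0)
  fe1 <- extract_features(im, compute_masks(im))
  fe2 <- extract_features(im2, compute_masks(im2))
  for (f in c("intensity_cell", "area_cell", "nuclear_percentage",
              "mean_pixel_nuc_cyto", "concentration_cell"))
    expect_equal(fe1[[f]], fe2[[f]], label = f)
})

test_that("image rendering and feature extraction agree with the truth", {
  cfg <- default_synthetic_config(n_cells_per_timepoint = 10, seed = 31,
                                  image_mode = TRUE)
  set.seed(31)
  for (i in 1:12) {
    ph <- cfg$phenotypes[[1 + (i %% 3)]]
    im <- generate_cell_image(ph, cfg, noise_sd = 0)
    fe <- extract_features(im, compute_masks(im))
    expect_lt(abs(fe$mean_pixel_nuc_cyto - im$truth$mean_pixel_nuc_cyto) /
                im$truth$mean_pixel_nuc_cyto, 0.05)
    expect_lt(abs(fe$concentration_cell - im$truth$concentration_cell) /
                im$truth$concentration_cell, 0.05)
  }
})

test_that("max_contour_position localizes central and peripheral signal", {
  im <- make_disk_image(lamp1_depth = 1.0)   # signal at the cell center
  m <- compute_masks(im)
  v <- max_contour_position(im$channels$lamp1, m$cell, n_rings = 8,
                            background = 5)
  expect_true(v$ok)
  expect_lte(v$value, 1 / 8)
  im2 <- make_disk_image(lamp1_depth = 0.02)  # signal at the boundary
  m2 <- compute_masks(im2)
  v2 <- max_contour_position(im2$channels$lamp1, m2$cell, n_rings = 8,
                             background = 5)
  expect_gte(v2$value, 1 - 1 / 8)
})

test_that("max_contour_position is monotone as signal moves outward", {
  depths <- seq(0.95, 0.05, length.out = 8)   # center -> boundary
  vals <- vapply(depths, function(dd) {
    im <- make_disk_image(lamp1_depth = dd)
    m <- compute_masks(im)
    max_contour_position(im$channels$lamp1, m$cell, n_rings = 8,
                         background = 5)$value
  }, numeric(1))
  expect_true(all(diff(vals) >= 0))
  expect_gt(vals[8], vals[1])
})

test_that("zero signal inside the mask yields the undefined sentinel", {
  im <- make_disk_image()
  m <- compute_masks(im)
  v <- max_contour_position(matrix(0, 64, 64), m$cell)
  expect_false(v$ok)
  expect_true(is.na(v$value))
  expect_error(max_contour_position(matrix(1, 4, 4),
                                    matrix(FALSE, 4, 4)), "empty")
})
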