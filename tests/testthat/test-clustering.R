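test_that("arcsinh transform matches its closed forms", {
  expect_equal(arcsinh_transform(0, 5), 0)
  expect_equal(arcsinh_transform(5, 5), log(1 + sqrt(2)))
  # asymptotic regime: asinh(x) ~ ln(2x) for large x
  expect_equal(arcsinh_transform(5000, 5), log(2 * 5000 / 5),
               tolerance = 1e-3)
  expect_error(arcsinh_transform(1, 0), "cofactor")
})

test_that("local density counts neighbors within the kernel radius", {
  # equally spaced line with the kernel shrunk below the spacing
  p <- cluster_params(neighborhood_size = 1, density_approx_factor = 0.5,
                      seed = 1)
  x <- matrix(seq(0, 9), ncol = 1)
  expect_true(all(local_density(x, p) == 1))
  # two tight blobs, 100 and 10 points: within-blob densities scale ~10x
  set.seed(2)
  big <- matrix(rnorm(200, 0, 0.01), ncol = 2)
  small <- matrix(rnorm(20, 8, 0.01), ncol = 2)
  d <- local_density(rbind(big, small), cluster_params(seed = 2))
  expect_equal(median(d[1:100]) / median(d[101:110]), 10, tolerance = 0.15)
  # identical points: all densities equal n
  xx <- matrix(1, 50, 2)
  expect_true(all(local_density(xx, cluster_params(seed = 3)) == 50))
})

test_that("duplicating every point doubles every density", {
  set.seed(3)
  x <- matrix(rnorm(400), ncol = 2)
  p <- cluster_params(seed = 4)
  d1 <- local_density(x, p)
  d2 <- local_density(rbind(x, x), p)
  expect_true(all(abs(d2[1:200] - 2 * d1) <= 1))
})

test_that("density downsampling follows the keep-probability rule", {
  p <- cluster_params(target_remaining = 100, max_pooled = 10000, seed = 5)
  set.seed(5)
  x <- matrix(rnorm(80), ncol = 1)
  # target >= n: no-op
  expect_identical(density_downsample(x, params = p), 1:80)

  # uniform densities: retained count concentrates at the target
  set.seed(6)
  xu <- matrix(runif(4000, 0, 100), ncol = 1)   # near-uniform density
  p2 <- cluster_params(target_remaining = 2000, max_pooled = 10000,
                       seed = 6)
  kept <- density_downsample(xu, params = p2)
  expect_lt(abs(length(kept) - 2000), 4 * sqrt(2000))
})

test_that("downsampling enriches the rare population (MC oracle)", {
  set.seed(7)
  n <- 4000
  maj <- matrix(rnorm(round(0.95 * n), 0, 0.05), ncol = 1)
  mino <- matrix(rnorm(round(0.05 * n), 3, 0.05), ncol = 1)
  x <- rbind(maj, mino)
  is_min <- c(rep(FALSE, nrow(maj)), rep(TRUE, nrow(mino)))
  p <- cluster_params(target_remaining = nrow(x) %/% 2,
                      max_pooled = 10000, seed = 7)
  dens <- local_density(x, p)
  kept <- density_downsample(x, dens, p)
  frac_min <- mean(is_min[kept])
  expect_gt(frac_min, 0.05)

  # Monte-Carlo oracle of the keep rule with the same densities
  expected <- function(td) sum(pmin(1, td / dens))
  lo <- 0; hi <- max(dens)
  for (i in 1:100) {
    mid <- (lo + hi) / 2
    if (expected(mid) < p$target_remaining) lo <- mid else hi <- mid
  }
  keep_prob <- pmin(1, hi / dens)
  set.seed(99)
  mc <- replicate(200, {
    k <- runif(length(dens)) < keep_prob
    mean(is_min[k])
  })
  expect_lt(abs(frac_min - mean(mc)), 4 * sd(mc) + 1e-6)
})

test_that("three separated components are recovered almost perfectly", {
  fx <- make_mixture_fixture(n = 3000, seed = 8)
  p <- cluster_params(k = 3, target_remaining = 2000, max_pooled = 10000,
                      seed = 8)
  m <- fit_cluster_model(fx$table, p)
  expect_equal(sort(as.numeric(m$centroids)), fx$t_means, tolerance = 0.1)
  acc <- best_match_accuracy(as.character(m$assignments),
                             as.character(fx$truth))
  expect_gte(acc, 0.99)
})

test_that("degenerate and duplicated inputs behave predictably", {
  fx <- make_mixture_fixture(n = 500, seed = 9)
  p1 <- cluster_params(k = 1, target_remaining = 1000, seed = 9)
  m1 <- fit_cluster_model(fx$table, p1)
  tx <- arcsinh_transform(fx$table$mean_pixel_nuc_cyto, 5)
  expect_equal(as.numeric(m1$centroids), mean(tx), tolerance = 1e-9)
  expect_true(all(m1$assignments == 1))

  # duplicated data: same centroids (k-means objective is invariant)
  p3 <- cluster_params(k = 3, target_remaining = 4000, seed = 10)
  m3 <- fit_cluster_model(fx$table, p3)
  dup <- rbind(fx$table, fx$table)
  m3d <- fit_cluster_model(dup, p3)
  expect_equal(m3$centroids, m3d$centroids, tolerance = 0.05)

  bad <- fx$table
  bad$mean_pixel_nuc_cyto[5] <- NA
  expect_error(fit_cluster_model(bad, p3), "non-finite")
  expect_error(fit_cluster_model(fx$table[1:2, ],
                                 cluster_params(k = 3, seed = 1)),
               "distinct")
})

test_that("restart count never worsens the best inertia", {
  fx <- make_mixture_fixture(n = 1500, seed = 11)
  inertia <- function(m, tab) {
    tx <- arcsinh_transform(as.matrix(tab[, m$params$features, drop = FALSE]),
                            m$params$arcsinh_cofactor)
    sum((tx - m$centroids[m$assignments, , drop = FALSE])^2)
  }
  p1 <- cluster_params(k = 3, n_restarts = 1, target_remaining = 2000,
                       seed = 12)
  p10 <- cluster_params(k = 3, n_restarts = 10, target_remaining = 2000,
                        seed = 12)
  i1 <- inertia(fit_cluster_model(fx$table, p1), fx$table)
  i10 <- inertia(fit_cluster_model(fx$table, p10), fx$table)
  expect_lte(i10, i1 + 1e-9)
})

test_that("fitting is fully deterministic given the seed", {
  fx <- make_mixture_fixture(n = 2000, seed = 13)
  p <- cluster_params(k = 3, target_remaining = 1500, seed = 13)
  m1 <- fit_cluster_model(fx$table, p)
  m2 <- fit_cluster_model(fx$table, p)
  expect_identical(m1$centroids, m2$centroids)
  expect_identical(m1$assignments, m2$assignments)
})

test_that("cluster labeling orders phenotypes by the ranking feature", {
  fx <- make_mixture_fixture(n = 3000, seed = 14)
  p <- cluster_params(k = 3, target_remaining = 2000, seed = 14)
  m <- label_clusters(fit_cluster_model(fx$table, p))
  means <- vapply(m$training_summary, function(s)
    s$means[["mean_pixel_nuc_cyto"]], numeric(1))
  expect_identical(m$label_map[order(means)],
                   c("Inactive", "Medium", "Active"))
  # k != 3 falls back to generic labels with a warning
  p2 <- cluster_params(k = 2, target_remaining = 2000, seed = 14)
  expect_warning(m2 <- label_clusters(fit_cluster_model(fx$table, p2)),
                 "k = 3")
  expect_identical(m2$label_map, c("C1", "C2"))
})

test_that("classification is idempotent, exact on centroids and transferable", {
  fx <- make_mixture_fixture(n = 4000, seed = 15)
  p <- cluster_params(k = 3, target_remaining = 3000, seed = 15)
  m <- label_clusters(fit_cluster_model(fx$table, p))
  lab1 <- classify_events(m, fx$table)
  expect_identical(attr(lab1, "cluster"), m$assignments)
  lab2 <- classify_events(m, fx$table)
  expect_identical(lab1, lab2)
  # an event exactly at a centroid gets that centroid's label
  back <- sinh(as.numeric(m$centroids)) * 5
  at_centroids <- data.frame(mean_pixel_nuc_cyto = back)
  expect_identical(as.character(classify_events(m, at_centroids)),
                   m$label_map)
  # held-out draw from the same generator recovers the weights
  fx2 <- make_mixture_fixture(n = 10000, seed = 16)
  lab3 <- classify_events(m, fx2$table)
  frac <- prop.table(table(factor(lab3, m$label_map)))
  band <- 4 * sqrt(fx2$weights * (1 - fx2$weights) / 10000) + 0.01
  expect_true(all(abs(as.numeric(frac) - fx2$weights) <= band))
  expect_error(classify_events(m, data.frame(x = 1)), "missing")
})

test_that("model files round-trip through the text format", {
  fx <- make_mixture_fixture(n = 1000, seed = 17)
  p <- cluster_params(k = 3, target_remaining = 800, seed = 17)
  m <- label_clusters(fit_cluster_model(fx$table, p))
  path <- tempfile(fileext = ".json")
  write_cluster_model(m, path)
  m2 <- read_cluster_model(path)
  expect_equal(m2$centroids, m$centroids)
  expect_identical(m2$label_map, m$label_map)
  expect_identical(classify_events(m2, fx$table),
                   classify_events(m, fx$table))
  expect_error(read_cluster_model(tempfile()), "no such file|cannot open")
})
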