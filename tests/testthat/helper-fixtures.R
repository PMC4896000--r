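# Shared fixture builders and independent oracles. Oracles are written as
# plain per-pixel loops / enumerations, deliberately independent of the
# package's vectorized implementations.

# A synthetic cell image with a circular cell, centered circular nucleus
# and uniform channel levels (plus optional noise), built directly from
# pixel coordinates without any package code.
make_disk_image <- function(size = 64, cell_r = 20, nuc_r = 10,
                            c_nuc = 30, c_cyto = 20, background = 5,
                            noise_sd = 0, lamp1_depth = NULL,
                            pixel_size_um = 0.5, center = NULL) {
  if (is.null(center)) center <- c(size / 2 + 0.5, size / 2 + 0.5)
  rr <- matrix(rep(seq_len(size), times = size), nrow = size)
  cc <- matrix(rep(seq_len(size), each = size), nrow = size)
  d <- sqrt((rr - center[1])^2 + (cc - center[2])^2)
  cell <- d <= cell_r
  nuc <- d <= nuc_r

  tfeb <- matrix(background, size, size)
  tfeb[cell & !nuc] <- background + c_cyto
  tfeb[nuc] <- background + c_nuc
  nuclear <- matrix(0, size, size)
  nuclear[nuc] <- 100
  bf <- matrix(100, size, size)
  bf[cell] <- 60
  lamp1 <- matrix(background, size, size)
  if (!is.null(lamp1_depth)) {
    # Ring of signal at a given normalized depth from the boundary
    # (0 = boundary, 1 = center).
    depth <- (cell_r - d) / cell_r
    ring <- cell & abs(depth - lamp1_depth) <= 0.06
    if (!any(ring)) ring <- cell & abs(depth - lamp1_depth) ==
        min(abs(depth[cell] - lamp1_depth))
    lamp1[ring] <- background + 50
  }
  if (noise_sd > 0) {
    n <- size * size
    tfeb <- pmax(tfeb + rnorm(n, 0, noise_sd), 0)
    nuclear <- pmax(nuclear + rnorm(n, 0, noise_sd), 0)
    lamp1 <- pmax(lamp1 + rnorm(n, 0, noise_sd), 0)
    bf <- pmax(bf + rnorm(n, 0, noise_sd), 0)
  }
  cell_image(list(brightfield = bf, nuclear_stain = nuclear,
                  tfeb = tfeb, lamp1 = lamp1),
             pixel_size_um = pixel_size_um)
}

# Brute-force threshold mask: enumerate prefixes of the descending-sorted
# pixel list, take the shortest whose sum reaches fraction * total, then
# include every pixel tied with the cutoff.
oracle_threshold_mask <- function(channel, fraction) {
  total <- sum(channel)
  out <- matrix(FALSE, nrow(channel), ncol(channel))
  if (total <= 0) return(out)
  v <- sort(as.numeric(channel), decreasing = TRUE)
  run <- 0
  m <- 0
  for (i in seq_along(v)) {
    run <- run + v[i]
    if (run >= fraction * total) { m <- i; break }
  }
  cutoff <- v[m]
  for (r in seq_len(nrow(channel))) for (cl in seq_len(ncol(channel)))
    if (channel[r, cl] >= cutoff) out[r, cl] <- TRUE
  out
}

# Brute-force feature computation by explicit per-pixel loops.
oracle_features <- function(image, masks) {
  ch <- image$channels
  pix_area <- image$pixel_size_um^2
  dil <- dilate_mask(masks$cell, 3L)
  bg_of <- function(channel) {
    s <- 0; n <- 0
    for (r in seq_len(nrow(channel))) for (cl in seq_len(ncol(channel)))
      if (!dil[r, cl]) { s <- s + channel[r, cl]; n <- n + 1 }
    if (n == 0) 0 else s / n
  }
  int_of <- function(channel, mask, bg) {
    s <- 0
    for (r in seq_len(nrow(channel))) for (cl in seq_len(ncol(channel)))
      if (mask[r, cl]) s <- s + max(channel[r, cl] - bg, 0)
    s
  }
  mean_of <- function(channel, mask, bg) {
    s <- 0; n <- 0
    for (r in seq_len(nrow(channel))) for (cl in seq_len(ncol(channel)))
      if (mask[r, cl]) { s <- s + max(channel[r, cl] - bg, 0); n <- n + 1 }
    if (n == 0) NA_real_ else s / n
  }
  bg_t <- bg_of(ch$tfeb)
  bg_l <- bg_of(ch$lamp1)
  ic <- int_of(ch$tfeb, masks$cell, bg_t)
  inu <- int_of(ch$tfeb, masks$nucleus, bg_t)
  icy <- int_of(ch$tfeb, masks$cytoplasm, bg_t)
  ac <- sum(masks$cell) * pix_area
  an <- sum(masks$nucleus) * pix_area
  acy <- sum(masks$cytoplasm) * pix_area
  mn <- mean_of(ch$tfeb, masks$nucleus_eroded, bg_t)
  mc <- mean_of(ch$tfeb, masks$cytoplasm_eroded, bg_t)
  list(intensity_cell = ic, intensity_nucleus = inu,
       intensity_cytoplasm = icy,
       area_cell = ac, area_nucleus = an, area_cytoplasm = acy,
       concentration_cell = if (ac > 0) ic / ac else 0,
       concentration_nucleus = if (an > 0) inu / an else 0,
       concentration_cytoplasm = if (acy > 0) icy / acy else 0,
       nuclear_percentage = if (ic > 0) 100 * inu / ic else 0,
       mean_pixel_nuc_cyto = if (!is.na(mn) && !is.na(mc) && mc > 0)
         mn / mc else NA_real_,
       lamp1_concentration = if (ac > 0)
         int_of(ch$lamp1, masks$cell, bg_l) / ac else 0)
}

# Best label accuracy over all permutations of cluster labels (exact
# optimal matching for small k).
best_match_accuracy <- function(pred, truth) {
  pl <- unique(pred); tl <- unique(truth)
  k <- length(pl)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  best <- 0
  for (p in perms(tl)) {
    mapping <- setNames(p[seq_len(k)], pl)
    best <- max(best, mean(mapping[pred] == truth))
  }
  best
}

# Small three-component 1-D mixture in raw space whose arcsinh-transformed
# means are >= 3 pooled SDs apart; returns the table plus the truth.
make_mixture_fixture <- function(n = 10000, seed = 42,
                                 weights = c(0.45, 0.46, 0.09),
                                 cofactor = 5) {
  set.seed(seed)
  t_means <- c(-1, 0, 1)     # transformed-space component centers
  t_sd <- 0.15               # pooled SD 0.15 -> separation ~6.7 SD
  lab <- sample(1:3, n, TRUE, weights)
  tx <- rnorm(n, t_means[lab], t_sd)
  raw <- sinh(tx) * cofactor
  list(table = data.frame(mean_pixel_nuc_cyto = raw,
                          treatment = "A", time_h = 0, replicate = 1L),
       truth = lab, t_means = t_means, weights = weights)
}
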