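# Per-channel background: mean intensity outside a 3-pixel dilation of the
# cell mask. Returns 0 when no outside pixels remain.
.estimate_background <- function(channel, cell_mask, dilation_px = 3L) {
  outside <- !dilate_mask(cell_mask, dilation_px)
  if (!any(outside)) return(0)
  mean(channel[outside])
}

# Background-subtracted sum over a mask, with per-pixel clipping at 0.
.masked_intensity <- function(channel, mask, background) {
  if (!any(mask)) return(0)
  sum(pmax(channel[mask] - background, 0))
}

#' Extract the full single-cell feature set
#'
#' Computes the per-event features used for phenotype clustering and
#' characterization: background-subtracted summed TFEB intensities over
#' the cell, nuclear and cytoplasmic masks; compartment areas in um^2;
#' concentrations (intensity per um^2); the nuclear percentage (100 x
#' nuclear/cell intensity); the pixel-mean nuclear/cytoplasmic ratio
#' computed on the eroded ("underestimated") masks; the LAMP1
#' concentration over the cell mask; the LAMP1 Max Contour Position; and
#' the brightfield gating features (area, aspect ratio, gradient RMS).
#'
#' Background per channel is the mean intensity outside a 3-pixel dilation
#' of the cell mask, and subtraction is clipped at zero per pixel.
#'
#' @param image A `cell_image`.
#' @param masks A `mask_set` from [compute_masks()]; must come from this
#'   image.
#' @param n_rings Number of radial rings for [max_contour_position()].
#' @param degenerate_ratio Value reported for `mean_pixel_nuc_cyto` when
#'   an eroded compartment is empty or has zero signal; such events are
#'   flagged (`ratio_ok = FALSE`) and excluded from clustering by default.
#' @return A one-row `data.frame` of features plus flags `ratio_ok` and
#'   `mcp_ok`.
#' @export
extract_features <- function(image, masks, n_rings = 8L,
                             degenerate_ratio = NA_real_) {
  stopifnot(inherits(image, "cell_image"), inherits(masks, "mask_set"))
  if (!masks$ok || !any(masks$cell))
    stop("empty cell mask: event is unanalyzable (gating failure)",
         call. = FALSE)
  ch <- image$channels
  pix_area <- image$pixel_size_um^2

  bg_tfeb <- .estimate_background(ch$tfeb, masks$cell)
  bg_lamp1 <- .estimate_background(ch$lamp1, masks$cell)

  int_cell <- .masked_intensity(ch$tfeb, masks$cell, bg_tfeb)
  int_nuc <- .masked_intensity(ch$tfeb, masks$nucleus, bg_tfeb)
  int_cyto <- .masked_intensity(ch$tfeb, masks$cytoplasm, bg_tfeb)

  area_cell <- sum(masks$cell) * pix_area
  area_nuc <- sum(masks$nucleus) * pix_area
  area_cyto <- sum(masks$cytoplasm) * pix_area

  conc <- function(int, area) if (area > 0) int / area else 0

  ratio_ok <- any(masks$nucleus_eroded) && any(masks$cytoplasm_eroded)
  if (ratio_ok) {
    mean_nuc <- mean(pmax(ch$tfeb[masks$nucleus_eroded] - bg_tfeb, 0))
    mean_cyto <- mean(pmax(ch$tfeb[masks$cytoplasm_eroded] - bg_tfeb, 0))
    ratio_ok <- mean_cyto > 0
    ratio <- if (ratio_ok) mean_nuc / mean_cyto else degenerate_ratio
  } else ratio <- degenerate_ratio

  mcp <- max_contour_position(ch$lamp1, masks$cell, n_rings = n_rings,
                              background = bg_lamp1)

  bf_inv <- max(ch$brightfield) - ch$brightfield
  bf_mask <- default_mask(bf_inv)
  bf_stats <- .mask_ellipse_stats(bf_mask)

  data.frame(
    intensity_cell = int_cell, intensity_nucleus = int_nuc,
    intensity_cytoplasm = int_cyto,
    area_cell = area_cell, area_nucleus = area_nuc,
    area_cytoplasm = area_cyto,
    concentration_cell = conc(int_cell, area_cell),
    concentration_nucleus = conc(int_nuc, area_nuc),
    concentration_cytoplasm = conc(int_cyto, area_cyto),
    nuclear_percentage = if (int_cell > 0) 100 * int_nuc / int_cell else 0,
    mean_pixel_nuc_cyto = ratio,
    lamp1_concentration = conc(
      .masked_intensity(ch$lamp1, masks$cell, bg_lamp1), area_cell),
    lamp1_max_contour_position = mcp$value,
    bf_area = sum(bf_mask) * pix_area,
    bf_aspect_ratio = bf_stats$aspect_ratio,
    bf_gradient_rms = gradient_rms(ch$brightfield),
    ratio_ok = ratio_ok,
    mcp_ok = mcp$ok,
    stringsAsFactors = FALSE
  )
}

# Best-fit-ellipse axis statistics of a mask from its pixel covariance;
# aspect ratio = minor/major in (0, 1]. Empty mask -> NA.
.mask_ellipse_stats <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) < 2)
    return(list(major = NA_real_, minor = NA_real_,
                aspect_ratio = NA_real_))
  cv <- stats::cov(idx)
  ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  # Axis lengths of the equivalent ellipse: 4 * sqrt(eigenvalue).
  major <- 4 * sqrt(ev[1]); minor <- 4 * sqrt(ev[2])
  list(major = major, minor = minor,
       aspect_ratio = if (major > 0) minor / major else 1)
}

#' Radial position of the highest-concentration contour
#'
#' Measures where in the cell a punctate signal concentrates: the mask is
#' partitioned into `n_rings` equal-width rings of normalized depth from
#' the boundary (depth 0) to the medial center (depth 1), the mean
#' background-subtracted intensity is computed per ring, and the value
#' returned is `1 - (normalized center depth of the argmax ring)`. Values
#' near 0 indicate a centered (perinuclear) distribution, values near 1 a
#' peripheral one. Ties are broken toward the more central ring (smaller
#' value).
#'
#' @param channel 2-D numeric matrix.
#' @param cell_mask Logical matrix, nonempty.
#' @param n_rings Number of rings, at least 2.
#' @param background Constant background subtracted (clipped at 0) before
#'   averaging.
#' @return List with `value` in \[0, 1\] (NA when the channel is zero
#'   inside the mask) and `ok` flag.
#' @export
max_contour_position <- function(channel, cell_mask, n_rings = 8L,
                                 background = 0) {
  stopifnot(is.matrix(channel), is.logical(cell_mask))
  if (!any(cell_mask)) stop("cell_mask is empty", call. = FALSE)
  if (n_rings < 2) stop("n_rings must be >= 2", call. = FALSE)
  sig <- pmax(channel - background, 0)
  if (sum(sig[cell_mask]) <= 0)
    return(list(value = NA_real_, ok = FALSE))
  dm <- EBImage::distmap(matrix(as.numeric(cell_mask), nrow(cell_mask),
                                ncol(cell_mask)))
  d <- dm[cell_mask]
  dmax <- max(d)
  depth <- if (dmax > 1) (d - 1) / (dmax - 1) else rep(0, length(d))
  ring <- pmin(floor(depth * n_rings) + 1L, n_rings)
  vals <- sig[cell_mask]
  ring_mean <- vapply(seq_len(n_rings), function(j) {
    inj <- ring == j
    if (any(inj)) mean(vals[inj]) else -Inf
  }, numeric(1))
  # Argmax with ties toward the deeper (more central) ring.
  best <- max(ring_mean)
  j <- max(which(ring_mean >= best - 1e-12))
  list(value = 1 - (j - 0.5) / n_rings, ok = TRUE)
}
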