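#' Default foreground mask for a fluorescence channel
#'
#' Stand-in for the instrument software's "default mask": global Otsu
#' threshold, 3x3 binary closing, then selection of the largest connected
#' foreground component. A constant channel yields an empty mask.
#'
#' @param channel 2-D numeric matrix with finite, nonnegative pixels.
#' @return Logical matrix of the same shape.
#' @export
default_mask <- function(channel) {
  stopifnot(is.matrix(channel))
  if (any(!is.finite(channel)) || any(channel < 0))
    stop("channel must be finite and nonnegative", call. = FALSE)
  rng <- range(channel)
  if (diff(rng) == 0)
    return(matrix(FALSE, nrow(channel), ncol(channel)))
  norm <- (channel - rng[1]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
  fg <- norm > thr
  fg <- EBImage::closing(EBImage::Image(fg * 1),
                         EBImage::makeBrush(3, shape = "box")) > 0.5
  fg <- matrix(as.logical(fg), nrow(channel), ncol(channel))
  if (!any(fg)) return(fg)
  lab <- EBImage::bwlabel(EBImage::Image(fg * 1))
  lab <- matrix(as.integer(lab), nrow(channel), ncol(channel))
  sizes <- tabulate(lab[lab > 0])
  lab == which.max(sizes)
}

#' Threshold mask capturing a fraction of total channel intensity
#'
#' Returns the smallest set of brightest pixels whose summed intensity
#' reaches at least `fraction` of the total channel intensity. Pixels are
#' admitted in descending intensity order; all pixels tied with the cutoff
#' intensity are included. This is the "70 % threshold" nuclear mask rule
#' applied to the DNA-stain channel.
#'
#' @param channel 2-D numeric matrix, finite and nonnegative.
#' @param fraction Fraction of total intensity to capture, in (0, 1\].
#' @return Logical matrix; empty when the channel is all zero.
#' @export
threshold_mask <- function(channel, fraction = 0.7) {
  stopifnot(is.matrix(channel))
  if (fraction <= 0 || fraction > 1)
    stop("fraction must lie in (0, 1]", call. = FALSE)
  total <- sum(channel)
  out <- matrix(FALSE, nrow(channel), ncol(channel))
  if (total <= 0) return(out)
  v <- sort(as.numeric(channel), decreasing = TRUE)
  csum <- cumsum(v)
  m <- which(csum >= fraction * total)[1]
  cutoff <- v[m]
  out[channel >= cutoff] <- TRUE
  out
}

# Disk-structuring-element morphology on logical masks. A radius of 0 is
# the identity. EBImage's "disc" brush of size 2r+1 is the digital disk of
# radius r.
.morph <- function(mask, radius, op = c("erode", "dilate")) {
  op <- match.arg(op)
  stopifnot(is.logical(mask))
  if (radius == 0) return(mask)
  brush <- EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
  img <- EBImage::Image(mask * 1)
  res <- if (op == "erode") EBImage::erode(img, brush)
         else EBImage::dilate(img, brush)
  matrix(as.numeric(res) > 0.5, nrow(mask), ncol(mask))
}

#' Erode or dilate a logical mask with a disk structuring element
#'
#' @param mask Logical matrix.
#' @param radius Disk radius in pixels (0 = identity).
#' @return Logical matrix.
#' @export
erode_mask <- function(mask, radius) .morph(mask, radius, "erode")

#' @rdname erode_mask
#' @export
dilate_mask <- function(mask, radius) .morph(mask, radius, "dilate")

#' Compartment masks for one cell event
#'
#' Implements the mask chain used for nuclear-translocation features:
#' * cell = default mask of the TFEB channel OR the 5-pixel erosion of the
#'   default brightfield mask (the brightfield channel shows a dark cell
#'   on a bright background and is inverted before masking);
#' * nucleus = 70% threshold mask of the DNA-stain channel, intersected
#'   with the cell mask;
#' * cytoplasm = cell AND NOT nucleus;
#' * eroded ("underestimated") nucleus and cytoplasm for the pixel-mean
#'   ratio, obtained by disk erosion; the eroded cytoplasm additionally
#'   excludes a dilation of the nucleus so that nuclear pixels can never
#'   leak into the cytoplasmic mean.
#'
#' @param image A `cell_image`.
#' @param erosion_px Disk radius (pixels) of the underestimating erosion.
#' @param nuclear_fraction Intensity fraction for the nuclear threshold
#'   mask.
#' @param bf_erosion_px Erosion depth applied to the brightfield mask
#'   before OR-ing it into the cell mask.
#' @return A `mask_set`: list of logical matrices `cell`, `nucleus`,
#'   `cytoplasm`, `nucleus_eroded`, `cytoplasm_eroded`, plus `ok` (FALSE
#'   when the cell mask is empty, i.e. the event is unanalyzable).
#' @export
compute_masks <- function(image, erosion_px = 2L, nuclear_fraction = 0.7,
                          bf_erosion_px = 5L) {
  stopifnot(inherits(image, "cell_image"))
  ch <- image$channels
  bf_inv <- max(ch$brightfield) - ch$brightfield
  bf_mask <- default_mask(bf_inv)
  cell <- default_mask(ch$tfeb) | erode_mask(bf_mask, bf_erosion_px)
  nucleus <- threshold_mask(ch$nuclear_stain, nuclear_fraction) & cell
  cytoplasm <- cell & !nucleus
  structure(list(
    cell = cell, nucleus = nucleus, cytoplasm = cytoplasm,
    nucleus_eroded = erode_mask(nucleus, erosion_px),
    cytoplasm_eroded = erode_mask(cell, erosion_px) &
      !dilate_mask(nucleus, erosion_px),
    ok = any(cell)
  ), class = "mask_set")
}

#' Gradient-RMS focus score
#'
#' Root mean square of the finite-difference gradient magnitude, computed
#' on the interior pixel grid (central differences). Sharper images score
#' higher; a constant image scores 0.
#'
#' @param channel 2-D numeric matrix, at least 3x3.
#' @return Nonnegative scalar.
#' @export
gradient_rms <- function(channel) {
  stopifnot(is.matrix(channel), nrow(channel) >= 3, ncol(channel) >= 3)
  nr <- nrow(channel); nc <- ncol(channel)
  gx <- (channel[, 3:nc, drop = FALSE] - channel[, 1:(nc - 2), drop = FALSE]) / 2
  gx <- gx[2:(nr - 1), , drop = FALSE]
  gy <- (channel[3:nr, , drop = FALSE] - channel[1:(nr - 2), , drop = FALSE]) / 2
  gy <- gy[, 2:(nc - 1), drop = FALSE]
  sqrt(mean(gx^2 + gy^2))
}
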