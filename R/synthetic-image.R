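# Rasterize an ellipse (pixel-center convention, 0-based centers stored as
# 1-based matrix indices) as a logical mask.
.ellipse_mask <- function(size, cx, cy, ax, ay, theta = 0) {
  xx <- matrix(rep(seq_len(size), each = size), nrow = size)   # column index
  yy <- matrix(rep(seq_len(size), times = size), nrow = size)  # row index
  dx <- xx - cx
  dy <- yy - cy
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  (u / ax)^2 + (v / ay)^2 <= 1
}

#' Render one synthetic cell as a multichannel image
#'
#' The cell body is a filled ellipse; the brightfield channel shows a dark
#' interior on a bright background, the nuclear-stain channel a uniform
#' nuclear disk, and the TFEB channel realizes the sampled
#' nuclear/cytoplasmic concentration ratio as two uniform per-pixel levels
#' plus a constant background and optional Gaussian pixel noise. The LAMP1
#' channel consists of punctate spots placed at the radial depth that
#' realizes the sampled Max Contour Position target (0 = center,
#' 1 = periphery). The true generating feature values are recorded in the
#' `truth` field.
#'
#' Per-pixel TFEB levels are `concentration * pixel_size_um^2`, so that
#' summed mask intensity divided by mask area (in um^2) recovers the
#' generating concentrations.
#'
#' @param phenotype A [phenotype_spec()]; used only when `truth` is NULL.
#' @param config A [synthetic_config()] with `image_mode` set.
#' @param truth Optional named list/row with fields `mean_pixel_nuc_cyto`,
#'   `concentration_cell`, `lamp1_concentration`,
#'   `lamp1_max_contour_position` (e.g. a row of [generate_features()]);
#'   when NULL, one cell is sampled from the phenotype using the current
#'   RNG state.
#' @param noise_sd Gaussian pixel noise SD added to every fluorescence
#'   channel (0 for noiseless rendering).
#' @param background Constant background level added to fluorescence
#'   channels.
#' @param n_spots Number of LAMP1 puncta.
#' @param metadata Optional named list merged into the result (cell_id,
#'   treatment, time_h, replicate).
#' @return A `cell_image`: list with `channels` (named list of matrices:
#'   brightfield, nuclear_stain, tfeb, lamp1), `pixel_size_um`, `truth`
#'   and metadata fields.
#' @export
generate_cell_image <- function(phenotype, config, truth = NULL,
                                noise_sd = 0, background = 5,
                                n_spots = 12L, metadata = list()) {
  stopifnot(inherits(config, "synthetic_config"))
  size <- config$image_size
  if (is.null(truth)) {
    z1 <- rnorm(1)
    z2 <- phenotype$conc_nc_corr * z1 +
      sqrt(1 - phenotype$conc_nc_corr^2) * rnorm(1)
    truth <- list(
      mean_pixel_nuc_cyto = exp(phenotype$log_nc_mean +
                                  phenotype$log_nc_sd * z1),
      concentration_cell = max(1e-6, phenotype$conc_mean +
                                 phenotype$conc_sd * z2),
      lamp1_concentration = max(1e-6, rnorm(1, phenotype$lamp1_conc_mean,
                                            phenotype$lamp1_conc_sd)),
      lamp1_max_contour_position = .rnorm_trunc(1, phenotype$mcp_mean,
                                                phenotype$mcp_sd, 0, 1),
      true_label = phenotype$label
    )
  }

  # Geometry: ellipse with mild eccentricity and jittered size; the frame
  # must contain the cell with a 4-pixel margin (background estimation
  # needs pixels outside the dilated cell mask).
  ax <- size * runif(1, 0.28, 0.33)
  ay <- ax * runif(1, 0.75, 0.9)
  theta <- runif(1, 0, pi)
  # The brightfield outline extends beyond the fluorescence signal by a
  # halo, as with a real transmitted-light cell boundary; the margin also
  # leaves room for background estimation outside the dilated cell mask.
  bf_halo <- 5
  margin <- 4
  if (max(ax, ay) + bf_halo + margin > size / 2)
    stop(sprintf(
      "cell (semi-axis %.1f px) exceeds frame; image_size >= %d required",
      max(ax, ay), ceiling(2 * (max(ax, ay) + bf_halo + margin))),
      call. = FALSE)
  cx <- size / 2 + 0.5
  cy <- size / 2 + 0.5
  cell <- .ellipse_mask(size, cx, cy, ax, ay, theta)

  a_frac <- if (!is.null(truth$area_nucleus) && !is.null(truth$area_cell))
    truth$area_nucleus / truth$area_cell else .rnorm_trunc(1, 0.35, 0.05,
                                                           0.15, 0.60)
  r_nuc <- sqrt(a_frac * ax * ay)
  nucleus <- .ellipse_mask(size, cx, cy, r_nuc, r_nuc)

  pix_area <- config$pixel_size_um^2
  rho <- truth$mean_pixel_nuc_cyto
  conc <- truth$concentration_cell
  a_eff <- sum(nucleus & cell) / sum(cell)
  c_cyto <- conc / (1 + a_eff * (rho - 1))
  c_nuc <- rho * c_cyto

  tfeb <- matrix(background, size, size)
  tfeb[cell & !nucleus] <- background + c_cyto * pix_area
  tfeb[nucleus & cell] <- background + c_nuc * pix_area

  nuclear_stain <- matrix(0, size, size)
  nuclear_stain[nucleus & cell] <- 100

  bf_body <- .ellipse_mask(size, cx, cy, ax + bf_halo, ay + bf_halo, theta)
  brightfield <- matrix(100, size, size)
  brightfield[bf_body] <- 60

  # LAMP1 puncta at the radial depth realizing the MCP target: depth 0 at
  # the cell boundary, 1 at the medial center; target position m puts the
  # spots at normalized depth 1 - m.
  lamp1 <- matrix(background, size, size)
  dm <- EBImage::distmap(matrix(as.numeric(cell), size, size))
  dmax <- max(dm)
  target_depth <- (1 - truth$lamp1_max_contour_position)
  target_d <- 1 + target_depth * (dmax - 1)
  inside <- which(cell & abs(dm - target_d) <= 0.75)
  if (!length(inside)) inside <- which(cell & dm >= 1)
  spots <- sample(inside, min(n_spots, length(inside)))
  spot_level <- truth$lamp1_concentration * pix_area * sum(cell) /
    max(1, length(spots))
  lamp1[spots] <- lamp1[spots] + spot_level

  if (noise_sd > 0) {
    npx <- size * size
    tfeb <- pmax(tfeb + rnorm(npx, 0, noise_sd), 0)
    nuclear_stain <- pmax(nuclear_stain + rnorm(npx, 0, noise_sd), 0)
    lamp1 <- pmax(lamp1 + rnorm(npx, 0, noise_sd), 0)
    brightfield <- pmax(brightfield + rnorm(npx, 0, noise_sd), 0)
  }

  structure(
    c(list(channels = list(brightfield = brightfield,
                           nuclear_stain = nuclear_stain,
                           tfeb = tfeb, lamp1 = lamp1),
           pixel_size_um = config$pixel_size_um,
           truth = truth),
      metadata),
    class = "cell_image"
  )
}

# Render every row of a generated feature table as a cell image.
render_condition_images <- function(config, features, noise_sd = 2) {
  lab_by <- setNames(config$phenotypes,
                     vapply(config$phenotypes, `[[`, character(1), "label"))
  lapply(seq_len(nrow(features)), function(i) {
    row <- as.list(features[i, ])
    generate_cell_image(lab_by[[row$true_label]], config, truth = row,
                        noise_sd = noise_sd,
                        metadata = row[c("cell_id", "treatment", "time_h",
                                         "replicate")])
  })
}

#' Construct a cell image from raw channel matrices
#'
#' @param channels Named list of equally sized numeric matrices; must
#'   include `brightfield`, `nuclear_stain`, `tfeb` and `lamp1`.
#' @param pixel_size_um Pixel size in micrometers.
#' @param ... Metadata fields (cell_id, treatment, time_h, replicate).
#' @return A `cell_image`.
#' @export
cell_image <- function(channels, pixel_size_um = 0.5, ...) {
  stopifnot(is.list(channels))
  need <- c("brightfield", "nuclear_stain", "tfeb", "lamp1")
  miss <- setdiff(need, names(channels))
  if (length(miss))
    stop("missing channel(s): ", paste(miss, collapse = ", "), call. = FALSE)
  dims <- vapply(channels, function(m) paste(dim(m), collapse = "x"),
                 character(1))
  if (length(unique(dims)) != 1L)
    stop("all channels must share the same shape", call. = FALSE)
  bad <- vapply(channels, function(m) any(!is.finite(m)) || any(m < 0),
                logical(1))
  if (any(bad))
    stop("channel(s) with non-finite or negative pixels: ",
         paste(names(channels)[bad], collapse = ", "), call. = FALSE)
  if (pixel_size_um <= 0) stop("pixel_size_um must be positive",
                               call. = FALSE)
  structure(c(list(channels = channels, pixel_size_um = pixel_size_um),
              list(...)),
            class = "cell_image")
}

#' Write or read synthetic image stacks as multi-page TIFF
#'
#' Each cell is written as one multi-page TIFF (one page per channel, in
#' the order brightfield, nuclear stain, TFEB, LAMP1). Pixel values are
#' rescaled to \[0, 1\] per channel for storage; the scale factors are
#' recorded in the sidecar metadata table (`metadata.tsv`) together with
#' cell id, treatment, time point, replicate and the true phenotype, so
#' reading restores the original values to float precision.
#'
#' @param images List of `cell_image` objects.
#' @param dir Output directory (created if needed).
#' @return `write_image_stacks` returns the sidecar path invisibly;
#'   `read_image_stacks` returns a list of `cell_image` objects.
#' @export
write_image_stacks <- function(images, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  chan_names <- c("brightfield", "nuclear_stain", "tfeb", "lamp1")
  rows <- lapply(seq_along(images), function(i) {
    im <- images[[i]]
    scales <- vapply(chan_names, function(ch) max(im$channels[[ch]], 1e-12),
                     numeric(1))
    pages <- lapply(chan_names, function(ch) im$channels[[ch]] /
                      max(im$channels[[ch]], 1e-12))
    fname <- sprintf("cell_%05d.tiff", i)
    tiff::writeTIFF(pages, file.path(dir, fname), bits.per.sample = 32L)
    data.frame(file = fname,
               cell_id = im$cell_id %||% sprintf("cell_%05d", i),
               treatment = im$treatment %||% NA_character_,
               time_h = im$time_h %||% NA_real_,
               replicate = im$replicate %||% NA_integer_,
               true_label = if (!is.null(im$truth)) im$truth$true_label
                            else NA_character_,
               pixel_size_um = im$pixel_size_um,
               scale_brightfield = scales[1], scale_nuclear_stain = scales[2],
               scale_tfeb = scales[3], scale_lamp1 = scales[4],
               stringsAsFactors = FALSE)
  })
  sidecar <- file.path(dir, "metadata.tsv")
  write.table(do.call(rbind, rows), sidecar, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(sidecar)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname write_image_stacks
#' @export
read_image_stacks <- function(dir) {
  sidecar <- file.path(dir, "metadata.tsv")
  if (!file.exists(sidecar))
    stop("no metadata.tsv sidecar in ", dir, call. = FALSE)
  meta <- read.delim(sidecar, stringsAsFactors = FALSE)
  chan_names <- c("brightfield", "nuclear_stain", "tfeb", "lamp1")
  lapply(seq_len(nrow(meta)), function(i) {
    pages <- tiff::readTIFF(file.path(dir, meta$file[i]), all = TRUE)
    scales <- as.numeric(meta[i, paste0("scale_", chan_names)])
    channels <- setNames(lapply(seq_along(chan_names), function(j)
      pages[[j]] * scales[j]), chan_names)
    cell_image(channels, pixel_size_um = meta$pixel_size_um[i],
               cell_id = meta$cell_id[i], treatment = meta$treatment[i],
               time_h = meta$time_h[i], replicate = meta$replicate[i],
               true_label = meta$true_label[i])
  })
}
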