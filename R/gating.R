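#' Gate configuration for single, in-focus cells
#'
#' @param area_min,area_max Brightfield mask area bounds in um^2.
#' @param aspect_ratio_min Minimum minor/major axis ratio of the
#'   brightfield mask's best-fit ellipse; doublets elongate the mask and
#'   drop below this.
#' @param gradient_rms_min Absolute minimum focus score, or `NULL` to use
#'   `gradient_rms_percentile`.
#' @param gradient_rms_percentile Percentile (0-100) of the observed focus
#'   scores used as the gate when no absolute minimum is given.
#' @return A `gate_config` list.
#' @export
gate_config <- function(area_min = 50, area_max = 500,
                        aspect_ratio_min = 0.6,
                        gradient_rms_min = NULL,
                        gradient_rms_percentile = 10) {
  structure(list(area_min = area_min, area_max = area_max,
                 aspect_ratio_min = aspect_ratio_min,
                 gradient_rms_min = gradient_rms_min,
                 gradient_rms_percentile = gradient_rms_percentile),
            class = "gate_config")
}

#' Gate events to single, in-focus cells
#'
#' Retains events passing all three gates: brightfield area within bounds,
#' brightfield aspect ratio (minor/major of the best-fit ellipse) above
#' the minimum, and gradient-RMS focus score above the minimum (absolute,
#' or a percentile of the batch when no absolute value is configured).
#'
#' @param events List of `cell_image` objects.
#' @param config A [gate_config()].
#' @return List with `retained` (the passing events), `report` (one row
#'   per event: gating features and per-gate pass flags) and `index` of
#'   retained events.
#' @export
gate_events <- function(events, config = gate_config()) {
  if (!length(events)) {
    warning("no events supplied to gate_events")
    return(list(retained = list(),
                report = data.frame(), index = integer(0)))
  }
  feats <- lapply(events, function(im) {
    bf <- im$channels$brightfield
    bf_mask <- default_mask(max(bf) - bf)
    st <- .mask_ellipse_stats(bf_mask)
    data.frame(bf_area = sum(bf_mask) * im$pixel_size_um^2,
               bf_aspect_ratio = st$aspect_ratio,
               bf_gradient_rms = gradient_rms(bf))
  })
  rep_df <- do.call(rbind, feats)
  grms_min <- config$gradient_rms_min
  if (is.null(grms_min))
    grms_min <- stats::quantile(rep_df$bf_gradient_rms,
                                config$gradient_rms_percentile / 100,
                                names = FALSE)
  rep_df$pass_area <- rep_df$bf_area >= config$area_min &
    rep_df$bf_area <= config$area_max
  rep_df$pass_aspect <- !is.na(rep_df$bf_aspect_ratio) &
    rep_df$bf_aspect_ratio >= config$aspect_ratio_min
  rep_df$pass_focus <- rep_df$bf_gradient_rms >= grms_min
  rep_df$pass <- rep_df$pass_area & rep_df$pass_aspect & rep_df$pass_focus
  idx <- which(rep_df$pass)
  list(retained = events[idx], report = rep_df, index = idx)
}
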