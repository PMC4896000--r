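# Deterministic sub-seed for a (treatment, time, replicate) cell draw, so
# that generate_features() called standalone reproduces the corresponding
# slice of generate_timecourse(). Kept below 2^31 - 1.
.stream_seed <- function(seed, trt_i, time_i, rep_i, salt = 0L) {
  m <- 2147483647
  s <- (as.numeric(seed) * 2654435.0 + trt_i * 97561 + time_i * 8191 +
          rep_i * 127 + salt * 31) %% m
  as.integer(s)
}

.logit <- function(p) log(p) - log1p(-p)
.inv_logit <- function(x) 1 / (1 + exp(-x))

# Logit-scale Gaussian jitter of a weight vector, renormalized back onto
# the simplex. Exact zeros stay zero (a phenotype absent from a condition
# does not reappear through replicate noise).
.jitter_weights <- function(w, sd, n = length(w)) {
  if (sd <= 0) return(w)
  pos <- w > 0 & w < 1
  x <- w
  x[pos] <- .inv_logit(.logit(w[pos]) + rnorm(sum(pos), 0, sd))
  x / sum(x)
}

.find_trajectory <- function(config, treatment) {
  for (tr in config$trajectories)
    if (tr$treatment == treatment) return(tr)
  stop(sprintf("unknown treatment '%s'; available: %s", treatment,
               paste(vapply(config$trajectories, `[[`, character(1),
                            "treatment"), collapse = ", ")),
       call. = FALSE)
}

# Per-replicate mixture weights for one (treatment, time), including the
# replicate jitter. Drawn from a dedicated RNG stream.
.replicate_weights <- function(config, treatment, time, replicate) {
  tr <- .find_trajectory(config, treatment)
  time_i <- match(time, tr$times)
  if (is.na(time_i))
    stop(sprintf("unknown time %g h for treatment '%s'; available: %s",
                 time, treatment, paste(tr$times, collapse = ", ")),
         call. = FALSE)
  w <- as.numeric(tr$weights[time_i, ])
  if (abs(sum(w) - 1) > 1e-9)
    stop("mixture weights do not sum to 1", call. = FALSE)
  trt_i <- match(treatment,
                 vapply(config$trajectories, `[[`, character(1), "treatment"))
  withr_seed <- .stream_seed(config$seed, trt_i, time_i, replicate, salt = 1L)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(withr_seed)
  .jitter_weights(w, config$replicate_jitter_sd)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

# Truncated normal via rejection-free clipping; adequate for marginals
# whose mass lies mostly inside the bounds (MCP, area fractions).
.rnorm_trunc <- function(n, mean, sd, lo, hi) {
  pmin(hi, pmax(lo, rnorm(n, mean, sd)))
}

#' Generating mixture weights for one replicate
#'
#' Returns the phenotype mixture weights actually used for a given
#' (treatment, time, replicate), i.e. the trajectory weights after the
#' replicate's logit-scale jitter. This is the generating truth that a
#' perfect classifier would recover (up to binomial sampling noise).
#'
#' @param config A [synthetic_config()].
#' @param treatment,time,replicate Condition identifiers.
#' @return Named numeric weight vector (one entry per phenotype).
#' @export
replicate_weights <- function(config, treatment, time, replicate = 1L) {
  stopifnot(inherits(config, "synthetic_config"))
  w <- .replicate_weights(config, treatment, time, replicate)
  setNames(w, vapply(config$phenotypes, `[[`, character(1), "label"))
}

#' Generate synthetic single-cell features for one condition
#'
#' Draws `n_cells_per_timepoint` cells for one (treatment, time,
#' replicate): the phenotype is sampled from the replicate-jittered
#' mixture weights; the log nuclear/cytoplasmic ratio and total TFEB
#' concentration are sampled from the phenotype's bivariate normal with
#' its within-phenotype correlation; LAMP1 concentration and Max Contour
#' Position come from the phenotype marginals (MCP truncated to \[0, 1\]).
#' All derived feature fields are mutually consistent: a nuclear/cell area
#' fraction is sampled per cell, compartment concentrations are solved
#' from the ratio and total concentration, and intensities, areas and the
#' nuclear percentage follow from those.
#'
#' @param config A [synthetic_config()].
#' @param treatment Treatment name present in the config.
#' @param time Time point in hours, present in the treatment's trajectory.
#' @param replicate Replicate index (1-based).
#' @return A `data.frame` with the standard feature columns, metadata and
#'   the ground-truth phenotype in `true_label`.
#' @export
generate_features <- function(config, treatment, time, replicate = 1L) {
  stopifnot(inherits(config, "synthetic_config"))
  w <- .replicate_weights(config, treatment, time, replicate)
  tr <- .find_trajectory(config, treatment)
  trt_i <- match(treatment,
                 vapply(config$trajectories, `[[`, character(1), "treatment"))
  time_i <- match(time, tr$times)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(.stream_seed(config$seed, trt_i, time_i, replicate, salt = 2L))

  n <- config$n_cells_per_timepoint
  k <- length(config$phenotypes)
  labels <- vapply(config$phenotypes, `[[`, character(1), "label")
  lab_i <- sample.int(k, n, replace = TRUE, prob = w)

  log_nc <- conc <- lamp1 <- mcp <- numeric(n)
  for (j in seq_len(k)) {
    idx <- which(lab_i == j)
    if (!length(idx)) next
    p <- config$phenotypes[[j]]
    z1 <- rnorm(length(idx))
    z2 <- p$conc_nc_corr * z1 +
      sqrt(1 - p$conc_nc_corr^2) * rnorm(length(idx))
    log_nc[idx] <- p$log_nc_mean + p$log_nc_sd * z1
    conc[idx] <- pmax(1e-6, p$conc_mean + p$conc_sd * z2)
    lamp1[idx] <- pmax(1e-6, rnorm(length(idx), p$lamp1_conc_mean,
                                   p$lamp1_conc_sd))
    mcp[idx] <- .rnorm_trunc(length(idx), p$mcp_mean, p$mcp_sd, 0, 1)
  }

  ratio <- exp(log_nc)
  # Nuclear/cell area fraction and cell size; compartment concentrations
  # solved so that the pixel-mean ratio and total concentration both hold.
  a_frac <- .rnorm_trunc(n, 0.35, 0.05, 0.15, 0.60)
  area_cell <- exp(rnorm(n, log(150), 0.15))
  area_nuc <- a_frac * area_cell
  area_cyto <- area_cell - area_nuc
  c_cyto <- conc / (1 + a_frac * (ratio - 1))
  c_nuc <- ratio * c_cyto

  df <- data.frame(
    cell_id = sprintf("%s_t%g_r%d_%05d", treatment, time, replicate,
                      seq_len(n)),
    treatment = treatment, time_h = time, replicate = as.integer(replicate),
    intensity_cell = conc * area_cell,
    intensity_nucleus = c_nuc * area_nuc,
    intensity_cytoplasm = c_cyto * area_cyto,
    area_cell = area_cell, area_nucleus = area_nuc,
    area_cytoplasm = area_cyto,
    concentration_cell = conc, concentration_nucleus = c_nuc,
    concentration_cytoplasm = c_cyto,
    nuclear_percentage = 100 * (c_nuc * area_nuc) / (conc * area_cell),
    mean_pixel_nuc_cyto = ratio,
    lamp1_concentration = lamp1,
    lamp1_max_contour_position = mcp,
    true_label = labels[lab_i],
    stringsAsFactors = FALSE
  )
  df
}

#' Generate the full synthetic multi-treatment time course
#'
#' Iterates [generate_features()] over every treatment, time point and
#' replicate in the config. Deterministic given the config seed. When
#' `image_mode` is set, each cell is also rendered as a multichannel image
#' and the list of images is attached as the `"images"` attribute.
#'
#' @param config A [synthetic_config()].
#' @param treatments Optional subset of treatment names.
#' @return An `experiment_table` (data.frame) with one row per cell.
#' @export
generate_timecourse <- function(config, treatments = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  all_trts <- vapply(config$trajectories, `[[`, character(1), "treatment")
  if (is.null(treatments)) treatments <- all_trts
  missing_t <- setdiff(treatments, all_trts)
  if (length(missing_t))
    stop("unknown treatment(s): ", paste(missing_t, collapse = ", "),
         call. = FALSE)
  parts <- list()
  images <- list()
  for (trt in treatments) {
    tr <- .find_trajectory(config, trt)
    for (time in tr$times) {
      for (rep_i in seq_len(config$n_replicates)) {
        df <- generate_features(config, trt, time, rep_i)
        parts[[length(parts) + 1L]] <- df
        if (config$image_mode) {
          images[[length(images) + 1L]] <- render_condition_images(
            config, df)
        }
      }
    }
  }
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out <- as_experiment_table(out, provenance = "synthetic")
  if (config$image_mode)
    attr(out, "images") <- do.call(c, images)
  out
}

#' Mark a feature data.frame as an experiment table
#'
#' An experiment table is a per-event feature table carrying complete
#' (treatment, time_h, replicate) metadata; the pipeline's orchestration
#' functions operate on this class.
#'
#' @param df A data.frame with metadata and feature columns.
#' @param provenance Free-text provenance note (`"synthetic"`, `"gated"`).
#' @return `df` with class `experiment_table`.
#' @export
as_experiment_table <- function(df, provenance = "unknown") {
  need <- c("treatment", "time_h", "replicate")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing metadata column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  class(df) <- c("experiment_table", "data.frame")
  attr(df, "provenance") <- provenance
  df
}
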