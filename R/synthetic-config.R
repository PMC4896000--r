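#' Describe one activation phenotype of the generator
#'
#' A phenotype is a component of the mixture model the synthetic generator
#' draws cells from. Its central quantity is the nuclear/cytoplasmic
#' TFEB concentration ratio ("Mean Pixel Nuc/Cyto"), modelled as lognormal
#' within a phenotype: ratios are positive and right-skewed in cytometry
#' data. Total TFEB concentration is jointly normal with the log ratio so
#' that nuclear localization and expression level can be correlated within
#' a phenotype. Lysosomal (LAMP1) concentration and the radial "Max
#' Contour Position" of the LAMP1 signal are drawn from phenotype-specific
#' marginals.
#'
#' @param label Phenotype name; `"Inactive"`, `"Medium"` or `"Active"` for
#'   the canonical three-state model.
#' @param log_nc_mean Mean of the natural-log nuclear/cytoplasmic
#'   concentration ratio (dimensionless).
#' @param log_nc_sd Its standard deviation; must be positive.
#' @param conc_mean Mean total TFEB concentration (intensity units per um^2).
#' @param conc_sd Its standard deviation; must be positive.
#' @param conc_nc_corr Correlation between the log ratio and total
#'   concentration within the phenotype, in \[-1, 1\].
#' @param lamp1_conc_mean Mean LAMP1 concentration (intensity per um^2).
#' @param lamp1_conc_sd Its standard deviation.
#' @param mcp_mean Target mean of the LAMP1 Max Contour Position, in
#'   \[0, 1\] (0 = perinuclear, 1 = peripheral).
#' @param mcp_sd Its standard deviation (draws are truncated to \[0, 1\]).
#' @return An object of class `phenotype_spec`.
#' @export
phenotype_spec <- function(label, log_nc_mean, log_nc_sd,
                           conc_mean, conc_sd, conc_nc_corr,
                           lamp1_conc_mean, lamp1_conc_sd = lamp1_conc_mean / 5,
                           mcp_mean = 0.6, mcp_sd = 0.2) {
  stopifnot(is.character(label), length(label) == 1L)
  if (!is.finite(log_nc_sd) || log_nc_sd <= 0)
    stop("log_nc_sd must be positive", call. = FALSE)
  if (!is.finite(conc_sd) || conc_sd <= 0)
    stop("conc_sd must be positive", call. = FALSE)
  if (abs(conc_nc_corr) > 1)
    stop("conc_nc_corr must lie in [-1, 1]", call. = FALSE)
  if (mcp_mean < 0 || mcp_mean > 1)
    stop("mcp_mean must lie in [0, 1]", call. = FALSE)
  structure(
    list(label = label, log_nc_mean = log_nc_mean, log_nc_sd = log_nc_sd,
         conc_mean = conc_mean, conc_sd = conc_sd,
         conc_nc_corr = conc_nc_corr,
         lamp1_conc_mean = lamp1_conc_mean, lamp1_conc_sd = lamp1_conc_sd,
         mcp_mean = mcp_mean, mcp_sd = mcp_sd),
    class = "phenotype_spec"
  )
}

#' Treatment-specific trajectory of phenotype mixture weights
#'
#' @param treatment Condition name (e.g. `"FM"`, `"Torin1"`, `"ND"`).
#' @param times Numeric vector of time points in hours, strictly increasing.
#' @param weights Matrix with one row per time point and one column per
#'   phenotype; each row must be nonnegative and sum to 1 (within 1e-9).
#' @return An object of class `mixture_trajectory`.
#' @export
mixture_trajectory <- function(treatment, times, weights) {
  weights <- as.matrix(weights)
  if (length(times) != nrow(weights))
    stop("one weight row per time point required", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  if (any(weights < 0))
    stop("mixture weights must be nonnegative", call. = FALSE)
  sums <- rowSums(weights)
  if (any(abs(sums - 1) > 1e-9))
    stop(sprintf(
      "weight rows must sum to 1 (worst deviation %.3g at time %g)",
      max(abs(sums - 1)), times[which.max(abs(sums - 1))]), call. = FALSE)
  structure(list(treatment = treatment, times = as.numeric(times),
                 weights = weights),
            class = "mixture_trajectory")
}

#' Full generative specification for the synthetic cytometry experiment
#'
#' @param phenotypes List of [phenotype_spec()] objects.
#' @param trajectories List of [mixture_trajectory()] objects; each weight
#'   matrix must have one column per phenotype.
#' @param n_cells_per_timepoint Cells generated per (treatment, time,
#'   replicate); the acquisition protocol collects 10000 events per
#'   condition and time point, with at least 2000 surviving gating.
#' @param n_replicates Independent experiments per condition.
#' @param replicate_jitter_sd SD of the Gaussian perturbation applied to
#'   the logit of each mixture weight, independently per replicate; keeps
#'   perturbed weights in the simplex after renormalization.
#' @param image_mode If `TRUE`, cells are rendered as multichannel images
#'   in addition to feature rows.
#' @param image_size Pixels per side of the square image frame.
#' @param pixel_size_um Physical pixel size in micrometers.
#' @param seed Integer random seed; the whole experiment is a
#'   deterministic function of the config.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(phenotypes, trajectories,
                             n_cells_per_timepoint = 10000L,
                             n_replicates = 3L,
                             replicate_jitter_sd = 0.15,
                             image_mode = FALSE,
                             image_size = 64L,
                             pixel_size_um = 0.5,
                             seed = 1L) {
  stopifnot(length(phenotypes) >= 1L, length(trajectories) >= 1L)
  if (n_cells_per_timepoint < 1)
    stop("n_cells_per_timepoint must be >= 1", call. = FALSE)
  if (image_mode && image_size < 32)
    stop("image_size must be >= 32 when image_mode is set", call. = FALSE)
  if (pixel_size_um <= 0)
    stop("pixel_size_um must be positive", call. = FALSE)
  labels <- vapply(phenotypes, `[[`, character(1), "label")
  if (anyDuplicated(labels))
    stop("phenotype labels must be unique", call. = FALSE)
  for (tr in trajectories) {
    if (ncol(tr$weights) != length(phenotypes))
      stop(sprintf(
        "trajectory '%s' has %d weight columns but %d phenotypes defined",
        tr$treatment, ncol(tr$weights), length(phenotypes)), call. = FALSE)
  }
  structure(
    list(phenotypes = phenotypes, trajectories = trajectories,
         n_cells_per_timepoint = as.integer(n_cells_per_timepoint),
         n_replicates = as.integer(n_replicates),
         replicate_jitter_sd = replicate_jitter_sd,
         image_mode = isTRUE(image_mode),
         image_size = as.integer(image_size),
         pixel_size_um = pixel_size_um,
         seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

#' Default three-phenotype TFEB activation experiment
#'
#' The shipped defaults emulate the measured structure of TFEB activation
#' in HeLa cells: three phenotypes whose mean nuclear/cytoplasmic ratios
#' (0.8, 1.5, 2.8) are well separated, a baseline mixture of 45/46/9
#' percent Inactive/Medium/Active, a pooled single-cell correlation of
#' about 0.53 between ratio and total concentration, a pooled correlation
#' of about -0.25 between the LAMP1 Max Contour Position and the ratio,
#' and LAMP1 concentration elevated by about 17 percent in the Active
#' phenotype. Three treatments are provided:
#'
#' * `FM` (fresh full medium, mTOR activation): the Inactive fraction
#'   surges to ~94% within 0.5 h and partially relaxes to 21/76/3 by 15 h.
#' * `Torin1` (mTOR inhibition): the Active fraction rises from 9% to 57%
#'   at 1.5 h and declines back to near baseline (47/45/8) by 15 h
#'   (rise-then-fall).
#' * `ND` (nutrient deprivation): starting from 80/17/3, an activation
#'   wave peaks at 1 h (18/56/25), re-inactivation empties the Active
#'   phenotype by 5 h, and a second activation wave follows by 15 h
#'   (rise-fall-rise).
#'
#' @param n_cells_per_timepoint Cells per (treatment, time, replicate);
#'   default 10000. Use `profile = "fast"` for the 2000-cell profile.
#' @param profile `"full"` (n = 10000) or `"fast"` (n = 2000).
#' @param seed Integer seed.
#' @param image_mode Render images as well as features.
#' @return A `synthetic_config`.
#' @export
default_synthetic_config <- function(n_cells_per_timepoint = NULL,
                                     profile = c("full", "fast"),
                                     seed = 1L, image_mode = FALSE) {
  profile <- match.arg(profile)
  if (is.null(n_cells_per_timepoint))
    n_cells_per_timepoint <- if (profile == "fast") 2000L else 10000L

  phenotypes <- list(
    phenotype_spec("Inactive", log_nc_mean = log(0.8), log_nc_sd = 0.12,
                   conc_mean = 85, conc_sd = 21.5, conc_nc_corr = 0.30,
                   lamp1_conc_mean = 100, lamp1_conc_sd = 20,
                   mcp_mean = 0.69, mcp_sd = 0.20),
    phenotype_spec("Medium", log_nc_mean = log(1.5), log_nc_sd = 0.12,
                   conc_mean = 100, conc_sd = 21.5, conc_nc_corr = 0.30,
                   lamp1_conc_mean = 100, lamp1_conc_sd = 20,
                   mcp_mean = 0.615, mcp_sd = 0.20),
    phenotype_spec("Active", log_nc_mean = log(2.8), log_nc_sd = 0.12,
                   conc_mean = 125, conc_sd = 21.5, conc_nc_corr = 0.30,
                   lamp1_conc_mean = 117, lamp1_conc_sd = 20,
                   mcp_mean = 0.52, mcp_sd = 0.20)
  )

  times <- c(0, 0.5, 1, 1.5, 3, 5, 15)
  fm <- rbind(
    c(0.45, 0.46, 0.09),   # baseline: 45/46/9
    c(0.94, 0.06, 0.00),   # near-complete inactivation at 0.5 h
    c(0.85, 0.14, 0.01),
    c(0.75, 0.23, 0.02),
    c(0.55, 0.42, 0.03),
    c(0.40, 0.57, 0.03),
    c(0.21, 0.76, 0.03))   # 21/76/3 at 15 h
  torin <- rbind(
    c(0.45, 0.46, 0.09),
    c(0.20, 0.45, 0.35),
    c(0.08, 0.43, 0.49),
    c(0.02, 0.41, 0.57),   # peak activation at 1.5 h: 2/41/57
    c(0.15, 0.45, 0.40),
    c(0.30, 0.46, 0.24),
    c(0.47, 0.45, 0.08))   # relaxed by 15 h: 47/45/8
  nd <- rbind(
    c(0.80, 0.17, 0.03),   # untreated baseline of this experiment
    c(0.40, 0.45, 0.15),
    c(0.18, 0.56, 0.26),   # first activation wave peaks at 1 h
    c(0.30, 0.55, 0.15),
    c(0.45, 0.50, 0.05),
    c(0.60, 0.40, 0.00),   # full loss of the Active phenotype at 5 h
    c(0.35, 0.50, 0.15))   # second activation wave by 15 h

  trajectories <- list(
    mixture_trajectory("FM", times, fm),
    mixture_trajectory("Torin1", times, torin),
    mixture_trajectory("ND", times, nd)
  )

  synthetic_config(phenotypes, trajectories,
                   n_cells_per_timepoint = n_cells_per_timepoint,
                   n_replicates = 3L,
                   replicate_jitter_sd = 0.15,
                   image_mode = image_mode,
                   seed = seed)
}

#' Read or write a synthetic configuration as YAML
#'
#' @param path File path.
#' @param config A `synthetic_config`.
#' @return `read_synthetic_config` returns a `synthetic_config`.
#' @export
read_synthetic_config <- function(path) {
  raw <- yaml::read_yaml(path)
  phenotypes <- lapply(raw$phenotypes, function(p) do.call(phenotype_spec, p))
  trajectories <- lapply(raw$trajectories, function(tr) {
    mixture_trajectory(tr$treatment, as.numeric(tr$times),
                       do.call(rbind, lapply(tr$weights, as.numeric)))
  })
  args <- raw[setdiff(names(raw), c("phenotypes", "trajectories"))]
  do.call(synthetic_config,
          c(list(phenotypes = phenotypes, trajectories = trajectories), args))
}

#' @rdname read_synthetic_config
#' @export
write_synthetic_config <- function(config, path) {
  stopifnot(inherits(config, "synthetic_config"))
  out <- list(
    phenotypes = lapply(config$phenotypes, function(p) unclass(p)),
    trajectories = lapply(config$trajectories, function(tr) {
      list(treatment = tr$treatment, times = tr$times,
           weights = lapply(seq_len(nrow(tr$weights)),
                            function(i) as.numeric(tr$weights[i, ])))
    }),
    n_cells_per_timepoint = config$n_cells_per_timepoint,
    n_replicates = config$n_replicates,
    replicate_jitter_sd = config$replicate_jitter_sd,
    image_mode = config$image_mode,
    image_size = config$image_size,
    pixel_size_um = config$pixel_size_um,
    seed = config$seed
  )
  yaml::write_yaml(out, path, precision = 17L)
  invisible(path)
}
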