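# Features whose within-cluster distributions are non-normal; these are
# compared with the Wilcoxon rank-sum test, concentration-type features
# with the t-test.
NONNORMAL_FEATURES <- c("mean_pixel_nuc_cyto", "lamp1_max_contour_position")

#' Pairwise inter-cluster comparisons on subsampled cells
#'
#' Compares a feature between every pair of clusters on seeded subsamples
#' of `n_subsample` cells per cluster (all cells when a cluster is
#' smaller, noted in the result). The test defaults to the Wilcoxon
#' rank-sum test (two-sided, normal approximation with tie correction)
#' for the non-normally distributed features - the nuclear/cytoplasmic
#' pixel ratio and the Max Contour Position - and to the two-tailed
#' Student t-test for concentration-type features. Raw p-values are
#' reported; set `adjust = "BH"` for a Benjamini-Hochberg correction.
#'
#' @param features Feature table.
#' @param assignments Per-event cluster labels.
#' @param feature Feature name to compare.
#' @param test `"auto"`, `"wilcoxon"` or `"t"`.
#' @param n_subsample Cells per cluster (default 1000).
#' @param seed Subsample seed.
#' @param adjust `"none"` (default: inter-cluster contrasts are conventionally reported uncorrected) or
#'   any method of [stats::p.adjust()].
#' @return Data.frame: group_a, group_b, test, statistic, p_value, n_a,
#'   n_b, seed, note.
#' @export
intercluster_test <- function(features, assignments, feature,
                              test = c("auto", "wilcoxon", "t"),
                              n_subsample = 1000L, seed = 1L,
                              adjust = "none") {
  test <- match.arg(test)
  if (test == "auto")
    test <- if (feature %in% NONNORMAL_FEATURES) "wilcoxon" else "t"
  df <- as.data.frame(features)
  labels <- sort(unique(assignments))
  if (length(labels) < 2)
    stop("need at least 2 clusters", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  rows <- list()
  for (i in seq_along(labels)) for (j in seq_len(i - 1L)) {
    a <- df[[feature]][assignments == labels[j]]
    b <- df[[feature]][assignments == labels[i]]
    note <- ""
    if (!length(a) || !length(b)) {
      rows[[length(rows) + 1L]] <- data.frame(
        group_a = labels[j], group_b = labels[i], test = test,
        statistic = NA_real_, p_value = NA_real_,
        n_a = length(a), n_b = length(b), seed = seed,
        note = "empty cluster; pair skipped", stringsAsFactors = FALSE)
      next
    }
    if (length(a) > n_subsample) a <- sample(a, n_subsample)
    else if (length(a) < n_subsample) note <- "cluster smaller than subsample"
    if (length(b) > n_subsample) b <- sample(b, n_subsample)
    else if (length(b) < n_subsample) note <- "cluster smaller than subsample"
    res <- if (test == "wilcoxon")
      suppressWarnings(wilcox.test(a, b, exact = FALSE))
    else t.test(a, b)
    rows[[length(rows) + 1L]] <- data.frame(
      group_a = labels[j], group_b = labels[i], test = test,
      statistic = unname(res$statistic), p_value = res$p.value,
      n_a = length(a), n_b = length(b), seed = seed, note = note,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (adjust != "none") out$p_value <- p.adjust(out$p_value, adjust)
  out
}

#' Compare a feature between two time points at the replicate level
#'
#' The testing unit is the replicate mean (typically n = 3 independent
#' experiments), not the single cell: per-cell testing at cytometry sample
#' sizes would declare trivial differences significant. A two-tailed
#' t-test compares the replicate means of `time` against `reference_time`
#' within a treatment.
#'
#' @param features Feature table with metadata.
#' @param treatment Treatment name.
#' @param time,reference_time Time points (hours) to compare.
#' @param feature Feature name.
#' @return Data.frame with the test name, statistic, p-value, replicate
#'   means and n per group; p is NA (not evaluable) with fewer than 2
#'   replicates.
#' @export
timepoint_test <- function(features, treatment, time, reference_time = 0,
                           feature = "mean_pixel_nuc_cyto") {
  df <- as.data.frame(features)
  pick <- function(tt) {
    sub <- df[df$treatment == treatment & df$time_h == tt, ]
    if (!nrow(sub))
      stop(sprintf("no events for treatment '%s' at %g h", treatment, tt),
           call. = FALSE)
    tapply(sub[[feature]], sub$replicate, mean)
  }
  a <- pick(time); b <- pick(reference_time)
  if (length(a) < 2 || length(b) < 2)
    return(data.frame(test = "t", statistic = NA_real_, p_value = NA_real_,
                      mean_a = mean(a), mean_b = mean(b),
                      n_a = length(a), n_b = length(b),
                      note = "fewer than 2 replicates; not evaluable",
                      stringsAsFactors = FALSE))
  if (sd(a) == 0 && sd(b) == 0) {
    # Degenerate case: no variability at either time point; identical
    # means are maximally non-significant, different means maximally so.
    p <- if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0
    return(data.frame(test = "t", statistic = NA_real_, p_value = p,
                      mean_a = mean(a), mean_b = mean(b),
                      n_a = length(a), n_b = length(b),
                      note = "zero variance in both groups",
                      stringsAsFactors = FALSE))
  }
  res <- t.test(a, b)
  data.frame(test = "t", statistic = unname(res$statistic),
             p_value = res$p.value, mean_a = mean(a), mean_b = mean(b),
             n_a = length(a), n_b = length(b), note = "",
             stringsAsFactors = FALSE)
}

#' Pooled single-cell Pearson correlation between two features
#'
#' Correlation over all pooled single cells, e.g. between the
#' nuclear/cytoplasmic ratio and the total concentration (positive:
#' cells with more TFEB tend to have it more nuclear) or between the
#' LAMP1 Max Contour Position and the ratio (negative: peripheral
#' lysosomes associate with low nuclear ratio).
#'
#' @param features Feature table.
#' @param x,y Feature names.
#' @return List with `r`, `n` and `ok` (`FALSE` with a reason when the
#'   correlation is undefined).
#' @export
single_cell_correlation <- function(features, x, y) {
  df <- as.data.frame(features)
  xv <- df[[x]]; yv <- df[[y]]
  keep <- is.finite(xv) & is.finite(yv)
  xv <- xv[keep]; yv <- yv[keep]
  if (length(xv) < 3)
    return(list(r = NA_real_, n = length(xv), ok = FALSE,
                reason = "fewer than 3 paired finite values"))
  if (sd(xv) == 0 || sd(yv) == 0)
    return(list(r = NA_real_, n = length(xv), ok = FALSE,
                reason = "zero variance"))
  list(r = cor(xv, yv), n = length(xv), ok = TRUE)
}
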