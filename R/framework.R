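#' Merge per-condition experiment tables for unbiased clustering
#'
#' Concatenates the tables and applies a seeded row shuffle, so that the
#' clustering stage sees all treatments and time points mixed together and
#' cannot exploit row ordering. Metadata is preserved per event; the
#' clustering features carry no treatment or time information themselves.
#'
#' @param tables List of `experiment_table` (or compatible data.frame)
#'   objects with identical columns.
#' @param seed Seed for the row shuffle.
#' @return A merged `experiment_table`.
#' @export
merge_experiments <- function(tables, seed = 1L) {
  if (!length(tables)) stop("empty list of tables", call. = FALSE)
  cols <- lapply(tables, names)
  ref <- cols[[1]]
  for (i in seq_along(cols)) {
    if (!identical(sort(cols[[i]]), sort(ref))) {
      extra <- setdiff(cols[[i]], ref)
      missing <- setdiff(ref, cols[[i]])
      stop(sprintf(
        "table %d columns differ from table 1 (extra: %s; missing: %s)",
        i, paste(extra, collapse = ", "),
        paste(missing, collapse = ", ")), call. = FALSE)
    }
  }
  tables <- lapply(tables, function(t) as.data.frame(t)[, ref, drop = FALSE])
  merged <- do.call(rbind, tables)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  merged <- merged[sample.int(nrow(merged)), , drop = FALSE]
  rownames(merged) <- NULL
  prov <- unique(unlist(lapply(tables, attr, "provenance")))
  as_experiment_table(merged,
                      provenance = paste(stats::na.omit(prov),
                                         collapse = "+"))
}

#' Subpopulation fractions per condition
#'
#' Computes, for every (treatment, time, replicate), the fraction of cells
#' assigned to each phenotype. Labels absent from a condition are reported
#' with fraction 0, so that every condition carries the full label set and
#' fractions sum to 1.
#'
#' @param assignments Character vector of per-event labels (e.g. from
#'   [classify_events()]).
#' @param table The `experiment_table` the assignments refer to.
#' @param labels Optional label universe; defaults to the labels observed.
#' @return A `subpop_timecourse` data.frame with columns treatment,
#'   time_h, replicate, label, fraction, n_cells.
#' @export
compute_timecourse <- function(assignments, table, labels = NULL) {
  df <- as.data.frame(table)
  if (length(assignments) != nrow(df))
    stop("one assignment per event required", call. = FALSE)
  if (is.null(labels)) labels <- sort(unique(assignments))
  key <- interaction(df$treatment, df$time_h, df$replicate, drop = TRUE)
  parts <- lapply(levels(key), function(kk) {
    idx <- key == kk
    n <- sum(idx)
    counts <- table(factor(assignments[idx], levels = labels))
    data.frame(treatment = df$treatment[idx][1],
               time_h = df$time_h[idx][1],
               replicate = df$replicate[idx][1],
               label = labels,
               fraction = as.numeric(counts) / n,
               n_cells = as.integer(counts),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  out <- out[order(out$treatment, out$time_h, out$replicate, out$label), ]
  rownames(out) <- NULL
  class(out) <- c("subpop_timecourse", "data.frame")
  out
}

# Replicate-averaged fraction time course: one row per (treatment, time,
# label).
.replicate_mean_tc <- function(tc) {
  agg <- aggregate(fraction ~ treatment + time_h + label,
                   data = as.data.frame(tc), FUN = mean)
  agg[order(agg$treatment, agg$time_h, agg$label), ]
}

#' Replicate-reproducibility criterion
#'
#' For each cluster, the metric is the mean over (treatment, time) of the
#' across-replicate standard deviation of its fraction. The criterion
#' passes when every cluster's metric is at or below the threshold: a
#' clustering whose subpopulation dynamics are not consistent among
#' repetitions is rejected.
#'
#' @param tc A `subpop_timecourse`.
#' @param threshold Maximum acceptable mean across-replicate SD of a
#'   fraction (default 0.10).
#' @return List with `metric` (named per cluster), `threshold`, `pass`
#'   and `evaluable`.
#' @export
evaluate_criterion1 <- function(tc, threshold = 0.10) {
  df <- as.data.frame(tc)
  n_rep <- length(unique(df$replicate))
  if (n_rep < 2)
    return(list(metric = NULL, threshold = threshold, pass = NA,
                evaluable = FALSE))
  sds <- aggregate(fraction ~ treatment + time_h + label, data = df,
                   FUN = sd)
  metric <- tapply(sds$fraction, sds$label, mean)
  list(metric = metric, threshold = threshold,
       pass = all(metric <= threshold), evaluable = TRUE)
}

#' Cluster-redundancy criterion
#'
#' For each pair of clusters, the Pearson correlation between their
#' replicate-averaged fraction time courses, concatenated across
#' treatments, is computed. A pair is flagged redundant when the
#' correlation is at or above `+r_threshold`: two clusters that respond
#' to every treatment in the same way do not represent distinct
#' phenotypes. Only positive co-movement counts - fractions are
#' compositional, so complementary clusters are necessarily
#' anticorrelated and negative correlations are expected, not redundant.
#' A cluster with a constant time course yields undefined correlations;
#' its pairs are reported unflagged with a note.
#'
#' @param tc A `subpop_timecourse`.
#' @param r_threshold Redundancy threshold on the correlation (default
#'   0.9).
#' @return List with `pairs` (data.frame: label_a, label_b, r, redundant,
#'   note), `r_threshold` and `pass`.
#' @export
evaluate_criterion2 <- function(tc, r_threshold = 0.9) {
  mtc <- .replicate_mean_tc(tc)
  labels <- sort(unique(mtc$label))
  n_time <- nrow(unique(mtc[, c("treatment", "time_h")]))
  if (n_time < 3)
    stop("criterion 2 requires at least 3 time points", call. = FALSE)
  series <- lapply(labels, function(l) {
    s <- mtc[mtc$label == l, ]
    s <- s[order(s$treatment, s$time_h), ]
    s$fraction
  })
  names(series) <- labels
  pairs <- list()
  for (i in seq_along(labels)) for (j in seq_len(i - 1L)) {
    a <- series[[labels[i]]]; b <- series[[labels[j]]]
    note <- ""
    if (sd(a) == 0 || sd(b) == 0) {
      r <- NA_real_
      note <- "constant time course; correlation undefined"
      red <- FALSE
    } else {
      r <- cor(a, b)
      red <- r >= r_threshold
    }
    pairs[[length(pairs) + 1L]] <- data.frame(
      label_a = labels[j], label_b = labels[i], r = r,
      redundant = red, note = note, stringsAsFactors = FALSE)
  }
  pairs <- do.call(rbind, pairs)
  list(pairs = pairs, r_threshold = r_threshold,
       pass = !any(pairs$redundant))
}

#' Search feature combinations and cluster numbers
#'
#' Runs the model-selection loop of the framework: for every candidate
#' (feature combination, k), a model is fitted on the merged data, the
#' subpopulation time course is computed, and the candidate is evaluated
#' against (a) the replicate-reproducibility criterion, (b) the
#' cluster-redundancy criterion, and (c) an inter-cluster separation
#' check: every adjacent cluster pair (ordered by the ranking feature)
#' must differ in the ranking-feature distribution by a two-sided Wilcoxon
#' rank-sum test on seeded 1000-cell subsamples at p <= 0.001.
#'
#' Among passing candidates, the selection prefers the fewest features,
#' then the largest k, then the lowest reproducibility metric. The
#' criteria bound the cluster number from above (irreproducible or
#' redundant clusters fail), so among sound models the one with the
#' fewest features and the finest phenotype resolution is chosen.
#'
#' @param merged Merged `experiment_table`.
#' @param feature_combos List of character vectors of feature names.
#' @param k_values Integer vector of candidate cluster numbers.
#' @param params Base [cluster_params()]; features and k are overridden
#'   per candidate.
#' @param c1_threshold,c2_threshold Criteria thresholds.
#' @param sep_p Separation-check significance level.
#' @param sep_n Subsample size per cluster for the separation check.
#' @param ranking_feature Feature used for cluster ordering, labeling and
#'   the separation check.
#' @return A `model_search_result`: list with `candidates` (data.frame of
#'   per-candidate outcomes), `reports` (full criteria reports), `selected`
#'   (index into candidates, or NA) and `model` (the selected, labeled
#'   `cluster_model`, or NULL).
#' @export
search_models <- function(merged, feature_combos, k_values,
                          params = cluster_params(),
                          c1_threshold = 0.10, c2_threshold = 0.9,
                          sep_p = 0.001, sep_n = 1000L,
                          ranking_feature = "mean_pixel_nuc_cyto") {
  if (!length(feature_combos) || !length(k_values))
    stop("empty candidate grid", call. = FALSE)
  cand <- expand.grid(combo = seq_along(feature_combos), k = k_values)
  rows <- list(); reports <- list(); models <- list()
  for (i in seq_len(nrow(cand))) {
    feats <- feature_combos[[cand$combo[i]]]
    k <- cand$k[i]
    p <- params
    p$features <- feats
    p$k <- as.integer(k)
    model <- fit_cluster_model(merged, p)
    labels <- classify_events(model, merged)
    tc <- compute_timecourse(labels, merged, labels = model$label_map)
    c1 <- evaluate_criterion1(tc, c1_threshold)
    c2 <- evaluate_criterion2(tc, c2_threshold)
    sep <- .separation_check(merged, labels, model, ranking_feature,
                             sep_n, sep_p, params$seed)
    pass <- isTRUE(c1$pass) && isTRUE(c2$pass) && sep$pass
    rows[[i]] <- data.frame(
      features = paste(feats, collapse = "+"), n_features = length(feats),
      k = k, c1_metric = max(c1$metric), c1_pass = isTRUE(c1$pass),
      c2_pass = isTRUE(c2$pass), sep_pass = sep$pass, pass = pass,
      stringsAsFactors = FALSE)
    reports[[i]] <- list(criterion1 = c1, criterion2 = c2,
                         separation = sep)
    models[[i]] <- model
  }
  candidates <- do.call(rbind, rows)
  passing <- which(candidates$pass)
  if (length(passing)) {
    ord <- order(candidates$n_features[passing],
                 -candidates$k[passing],
                 candidates$c1_metric[passing])
    sel <- passing[ord[1]]
    model <- label_clusters(models[[sel]], ranking_feature)
  } else {
    sel <- NA_integer_
    model <- NULL
  }
  candidates$selected <- seq_len(nrow(candidates)) %in% sel
  structure(list(candidates = candidates, reports = reports,
                 selected = sel, model = model),
            class = "model_search_result")
}

# Adjacent-cluster separation check: clusters ordered by their training
# mean of the ranking feature; each adjacent pair must differ by Wilcoxon
# on seeded subsamples.
.separation_check <- function(merged, labels, model, ranking_feature,
                              n_sub, p_max, seed) {
  df <- as.data.frame(merged)
  idx <- attr(labels, "cluster")
  k <- model$params$k
  means <- vapply(model$training_summary, function(s)
    s$means[[ranking_feature]], numeric(1))
  ord <- order(means)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed + 17L)
  pvals <- numeric(0)
  if (k >= 2) for (a in seq_len(k - 1)) {
    g1 <- df[[ranking_feature]][idx == ord[a]]
    g2 <- df[[ranking_feature]][idx == ord[a + 1]]
    if (!length(g1) || !length(g2)) { pvals <- c(pvals, 1); next }
    if (length(g1) > n_sub) g1 <- sample(g1, n_sub)
    if (length(g2) > n_sub) g2 <- sample(g2, n_sub)
    pvals <- c(pvals, suppressWarnings(
      wilcox.test(g1, g2, exact = FALSE)$p.value))
  }
  list(pvals = pvals, p_max = p_max,
       pass = k < 2 || all(pvals <= p_max))
}

#' Predict the mean population response from subpopulations
#'
#' Reconstructs the mean of a feature per (treatment, time, replicate) as
#' the fraction-weighted sum of per-cluster means. In `"per-condition"`
#' mode the cluster means are computed within each condition from the same
#' events, and the prediction reproduces the direct event mean exactly
#' (the weighted-mean decomposition identity). In `"global"` mode a single
#' set of cluster means (over all conditions) is used, and the deviation
#' from the direct mean is reported as a residual diagnostic: it measures
#' how much of the mean response is explained by redistribution among
#' fixed phenotypes alone.
#'
#' @param tc A `subpop_timecourse`.
#' @param table The `experiment_table` with the feature values.
#' @param assignments Per-event labels matching `table`.
#' @param feature Feature name to decompose.
#' @param mode `"per-condition"` or `"global"`.
#' @return Data.frame per (treatment, time_h, replicate): `predicted`,
#'   `direct`, `residual`.
#' @export
predict_mean_from_subpops <- function(tc, table, assignments,
                                      feature = "mean_pixel_nuc_cyto",
                                      mode = c("per-condition", "global")) {
  mode <- match.arg(mode)
  df <- as.data.frame(table)
  if (length(assignments) != nrow(df))
    stop("one assignment per event required", call. = FALSE)
  tcd <- as.data.frame(tc)
  conds <- unique(tcd[, c("treatment", "time_h", "replicate")])
  labels <- unique(tcd$label)

  global_means <- if (mode == "global")
    tapply(df[[feature]], factor(assignments, levels = labels), mean)
  else NULL

  out <- lapply(seq_len(nrow(conds)), function(i) {
    trt <- conds$treatment[i]; tt <- conds$time_h[i]
    rr <- conds$replicate[i]
    in_cond <- df$treatment == trt & df$time_h == tt & df$replicate == rr
    if (!any(in_cond))
      stop(sprintf("no events for condition (%s, %g, %s)", trt, tt, rr),
           call. = FALSE)
    fr <- tcd[tcd$treatment == trt & tcd$time_h == tt &
                tcd$replicate == rr, ]
    fr <- setNames(fr$fraction, fr$label)
    cl_means <- if (mode == "global") global_means
    else tapply(df[[feature]][in_cond],
                factor(assignments[in_cond], levels = labels), mean)
    cl_means[is.na(cl_means)] <- 0
    predicted <- sum(fr[labels] * cl_means[labels])
    direct <- mean(df[[feature]][in_cond])
    data.frame(treatment = trt, time_h = tt, replicate = rr,
               predicted = predicted, direct = direct,
               residual = predicted - direct, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Annotate response regions of a subpopulation time course
#'
#' Heuristic segmentation of the time axis for reporting: the
#' replicate-averaged trajectory of the chosen phenotype (default: the
#' Active fraction) is optionally smoothed by a short moving average, and
#' region boundaries are placed where the sign of its discrete derivative
#' changes. A monotone trajectory yields one region; rise-then-fall
#' yields two (boundary at the empirical peak); rise-fall-rise yields
#' three. Annotations are labeled R1, R2, ... and have no effect on any
#' statistic.
#'
#' @param tc A `subpop_timecourse`.
#' @param treatment Treatment to annotate.
#' @param label Phenotype whose trajectory drives the segmentation.
#' @param smooth_window Moving-average window (odd, in time points; 1 =
#'   no smoothing).
#' @param min_change Minimum fraction change between consecutive time
#'   points to count as a rise or fall (suppresses noise-level sign
#'   flips).
#' @return Data.frame of regions: region, t_start, t_end, direction; or
#'   NULL (with a warning) when fewer than 3 time points are available.
#' @export
annotate_regions <- function(tc, treatment, label = "Active",
                             smooth_window = 1L, min_change = 0.01) {
  mtc <- .replicate_mean_tc(tc)
  s <- mtc[mtc$treatment == treatment & mtc$label == label, ]
  s <- s[order(s$time_h), ]
  if (nrow(s) < 3) {
    warning("too few time points to annotate regions")
    return(NULL)
  }
  y <- s$fraction
  if (smooth_window > 1) {
    kk <- rep(1 / smooth_window, smooth_window)
    pad <- (smooth_window - 1) / 2
    yp <- c(rep(y[1], pad), y, rep(y[length(y)], pad))
    y <- as.numeric(stats::filter(yp, kk, sides = 2))[pad + seq_along(y)]
  }
  d <- diff(y)
  dir <- sign(d) * (abs(d) >= min_change)
  # Carry forward the last nonzero direction over flat stretches.
  for (i in seq_along(dir)) if (dir[i] == 0 && i > 1) dir[i] <- dir[i - 1]
  change <- which(diff(dir) != 0 & dir[-1] != 0) + 1L
  bounds <- c(1L, change, length(s$time_h))
  regions <- lapply(seq_len(length(bounds) - 1L), function(i) {
    seg <- dir[bounds[i]:(bounds[i + 1] - 1L)]
    data.frame(region = paste0("R", i),
               t_start = s$time_h[bounds[i]],
               t_end = s$time_h[bounds[i + 1]],
               direction = if (all(seg >= 0)) "rise"
                           else if (all(seg <= 0)) "fall" else "mixed",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, regions)
}
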