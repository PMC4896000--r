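# Small deterministic subpop_timecourse builder used by the criteria tests.
make_tc <- function(fractions_fun, treatments = "T1",
                    times = c(0, 1, 2, 5), replicates = 1:3,
                    labels = c("Inactive", "Medium", "Active")) {
  rows <- list()
  for (trt in treatments) for (tt in times) for (rr in replicates) {
    fr <- fractions_fun(trt, tt, rr)
    rows[[length(rows) + 1L]] <- data.frame(
      treatment = trt, time_h = tt, replicate = rr, label = labels,
      fraction = fr, n_cells = round(fr * 1000), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("subpop_timecourse", "data.frame")
  out
}

test_that("merging concatenates tables and validates columns", {
  cfg <- default_synthetic_config(n_cells_per_timepoint = 100, seed = 1)
  a <- generate_features(cfg, "FM", 0, 1)
  b <- generate_features(cfg, "Torin1", 0, 1)
  m <- merge_experiments(list(as_experiment_table(a),
                              as_experiment_table(b)), seed = 1)
  expect_equal(nrow(m), 200)
  expect_setequal(names(m), names(a))
  expect_equal(sort(m$cell_id), sort(c(a$cell_id, b$cell_id)))
  expect_error(merge_experiments(list()), "empty")
  b2 <- b; b2$extra <- 1
  expect_error(merge_experiments(list(a, b2)), "extra")
})

test_that("merging a table with itself leaves centroids unchanged", {
  fx <- make_mixture_fixture(n = 1500, seed = 3)
  tab <- as_experiment_table(fx$table)
  p <- cluster_params(k = 3, target_remaining = 4000, seed = 3)
  m1 <- fit_cluster_model(merge_experiments(list(tab), seed = 3), p)
  m2 <- fit_cluster_model(merge_experiments(list(tab, tab), seed = 3), p)
  expect_equal(m1$centroids, m2$centroids, tolerance = 0.05)
})

test_that("time-course fractions are exact count ratios", {
  n <- 1000
  df <- data.frame(
    treatment = "T1", time_h = 0, replicate = 1L,
    stringsAsFactors = FALSE)[rep(1, n), ]
  lab <- rep(c("Inactive", "Medium", "Active"), times = c(450, 460, 90))
  tc <- compute_timecourse(lab, as_experiment_table(df))
  expect_equal(sum(tc$fraction), 1, tolerance = 1e-12)
  expect_equal(tc$fraction[tc$label == "Inactive"], 0.45)
  expect_equal(tc$fraction[tc$label == "Medium"], 0.46)
  expect_equal(tc$fraction[tc$label == "Active"], 0.09)
  # fractions times n reproduce integer counts
  expect_equal(tc$fraction * n, tc$n_cells)
  # absent labels are reported with fraction zero
  tc2 <- compute_timecourse(rep("Medium", n), as_experiment_table(df),
                            labels = c("Inactive", "Medium", "Active"))
  expect_equal(tc2$fraction[tc2$label == "Medium"], 1)
  expect_equal(tc2$fraction[tc2$label != "Medium"], c(0, 0))
})

test_that("criterion 1 separates consistent from scrambled replicates", {
  base <- function(trt, tt, rr) {
    w <- c(0.45, 0.46, 0.09) + c(-1, 1, 0) * 0.02 * tt / 5
    w / sum(w)
  }
  tc <- make_tc(base)
  c1 <- evaluate_criterion1(tc)
  expect_true(c1$evaluable)
  expect_equal(unname(as.numeric(c1$metric)), c(0, 0, 0))
  expect_true(c1$pass)

  # permute one replicate's fractions across clusters: inconsistency
  scram <- function(trt, tt, rr) {
    w <- base(trt, tt, rr)
    if (rr == 2) w <- w[c(3, 1, 2)]
    w
  }
  c1s <- evaluate_criterion1(make_tc(scram))
  expect_false(c1s$pass)
  expect_gt(max(c1s$metric), 0.1)

  one_rep <- make_tc(base, replicates = 1)
  expect_false(evaluate_criterion1(one_rep)$evaluable)
})

test_that("criterion 2 flags positive co-movement only", {
  # two clusters share identical dynamics; third takes the complement
  dup <- function(trt, tt, rr) {
    a <- 0.2 + 0.1 * sin(tt)
    c(a, a, 1 - 2 * a)
  }
  c2 <- evaluate_criterion2(make_tc(dup))
  expect_false(c2$pass)
  flagged <- c2$pairs[c2$pairs$redundant, ]
  expect_true(nrow(flagged) >= 1)
  expect_true(any(abs(flagged$r - 1) < 1e-9))

  # mirror dynamics (r = -1) must not be flagged
  mirror <- function(trt, tt, rr) {
    a <- 0.3 + 0.1 * sin(tt)
    c(a, 0.6 - a, 0.4)
  }
  c2m <- evaluate_criterion2(make_tc(mirror))
  expect_true(c2m$pass)
  # the constant third cluster yields undefined correlations, noted
  expect_true(any(grepl("constant", c2m$pairs$note)))
})

test_that("per-condition decomposition reproduces the direct mean exactly", {
  cfg <- default_synthetic_config(n_cells_per_timepoint = 400, seed = 5)
  tab <- generate_timecourse(cfg, treatments = "Torin1")
  # any labeling whatsoever satisfies the identity
  set.seed(5)
  lab <- sample(c("A", "B", "C"), nrow(tab), TRUE)
  tc <- compute_timecourse(lab, tab)
  dec <- predict_mean_from_subpops(tc, tab, lab,
                                   feature = "mean_pixel_nuc_cyto",
                                   mode = "per-condition")
  expect_lt(max(abs(dec$residual)), 1e-9)
  expect_equal(dec$predicted, dec$direct, tolerance = 1e-12)

  # single-cluster population: prediction equals that cluster's mean
  lab1 <- rep("only", nrow(tab))
  tc1 <- compute_timecourse(lab1, tab)
  dec1 <- predict_mean_from_subpops(tc1, tab, lab1, mode = "per-condition")
  expect_lt(max(abs(dec1$residual)), 1e-9)

  # global means: residual bounded by within-condition drift of cluster
  # means, computed directly from the events
  lab3 <- classify_events(
    label_clusters(fit_cluster_model(
      tab, cluster_params(k = 3, target_remaining = 8000, seed = 5))), tab)
  tc3 <- compute_timecourse(lab3, tab, labels = c("Inactive", "Medium",
                                                  "Active"))
  dec3 <- predict_mean_from_subpops(tc3, tab, lab3, mode = "global")
  gmean <- tapply(tab$mean_pixel_nuc_cyto, lab3, mean)
  drift <- by(data.frame(v = tab$mean_pixel_nuc_cyto, l = lab3),
              interaction(tab$treatment, tab$time_h, tab$replicate,
                          drop = TRUE),
              function(d) max(abs(tapply(d$v, factor(d$l, names(gmean)),
                                         mean) - gmean), na.rm = TRUE))
  expect_lte(max(abs(dec3$residual)), max(unlist(drift)))
})

test_that("region annotation segments trajectories by shape", {
  mono <- function(trt, tt, rr) {
    a <- 0.1 + 0.05 * tt
    c(1 - a - 0.3, 0.3, a)
  }
  r1 <- annotate_regions(make_tc(mono), "T1")
  expect_equal(nrow(r1), 1)
  expect_equal(r1$direction, "rise")

  rise_fall <- function(trt, tt, rr) {
    a <- c(`0` = 0.09, `1` = 0.57, `2` = 0.4, `5` = 0.1)[as.character(tt)]
    c((1 - a) / 2, (1 - a) / 2, a)
  }
  r2 <- annotate_regions(make_tc(rise_fall), "T1")
  expect_equal(nrow(r2), 2)
  expect_equal(r2$t_end[1], 1)   # boundary at the empirical peak
  expect_equal(r2$direction, c("rise", "fall"))

  rfr <- function(trt, tt, rr) {
    a <- c(`0` = 0.03, `1` = 0.25, `2` = 0.05, `5` = 0.20)[as.character(tt)]
    c((1 - a) / 2, (1 - a) / 2, a)
  }
  r3 <- annotate_regions(make_tc(rfr), "T1")
  expect_equal(nrow(r3), 3)
  expect_equal(r3$direction, c("rise", "fall", "rise"))

  short <- make_tc(mono, times = c(0, 1))
  expect_warning(r0 <- annotate_regions(short, "T1"), "too few")
  expect_null(r0)
})

test_that("model search honours the candidate grid and is reproducible", {
  cfg <- default_synthetic_config(n_cells_per_timepoint = 400, seed = 6)
  tab <- generate_timecourse(cfg, treatments = c("FM", "Torin1"))
  merged <- merge_experiments(list(tab), seed = 6)
  p <- cluster_params(max_pooled = 20000, target_remaining = 6000,
                      seed = 6)
  # single passing candidate is selected
  s1 <- search_models(merged, list("mean_pixel_nuc_cyto"), 3L, params = p)
  expect_equal(s1$selected, 1L)
  expect_true(s1$candidates$pass[1])
  expect_s3_class(s1$model, "cluster_model")
  # rerun reproduces the same selection and centroids
  s2 <- search_models(merged, list("mean_pixel_nuc_cyto"), 3L, params = p)
  expect_identical(s1$model$centroids, s2$model$centroids)
  expect_error(search_models(merged, list(), integer(0)), "empty")
})

test_that("model selection is invariant under event-order permutation", {
  cfg <- default_synthetic_config(n_cells_per_timepoint = 300, seed = 8)
  tab <- generate_timecourse(cfg, treatments = c("FM", "Torin1"))
  p <- cluster_params(max_pooled = 20000, target_remaining = 5000,
                      seed = 8)
  m1 <- merge_experiments(list(tab), seed = 8)
  set.seed(123)
  tab_perm <- tab[sample.int(nrow(tab)), ]
  m2 <- merge_experiments(list(as_experiment_table(tab_perm)), seed = 8)
  grid <- list("mean_pixel_nuc_cyto")
  s1 <- search_models(m1, grid, c(2L, 3L), params = p)
  s2 <- search_models(m2, grid, c(2L, 3L), params = p)
  expect_identical(s1$candidates$features[s1$selected],
                   s2$candidates$features[s2$selected])
  expect_identical(s1$candidates$k[s1$selected],
                   s2$candidates$k[s2$selected])
})
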