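#' Export the analysis report bundle
#'
#' Writes the machine-readable twin of the figure panels: delimited
#' tables of subpopulation fractions, per-cluster phenotype summaries,
#' statistical test results and pooled correlations, plus a run manifest
#' (config hash, seed, package version, file inventory) that allows an
#' exact, byte-identical rerun.
#'
#' @param dir Output directory (created if needed).
#' @param timecourse A `subpop_timecourse` (optional).
#' @param cluster_summary Data.frame of per-cluster feature summaries
#'   (optional).
#' @param tests Data.frame of test results (optional).
#' @param correlations Data.frame of correlation results (optional).
#' @param config_path Path of the configuration that produced the run
#'   (hashed into the manifest when given).
#' @param seed The run seed recorded in the manifest.
#' @return Invisibly, the manifest path.
#' @export
export_report <- function(dir, timecourse = NULL, cluster_summary = NULL,
                          tests = NULL, correlations = NULL,
                          config_path = NULL, seed = NA_integer_) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  emit <- function(df, name) {
    if (is.null(df)) return(invisible(NULL))
    p <- file.path(dir, name)
    write.table(as.data.frame(df), p, sep = "\t", quote = FALSE,
                row.names = FALSE)
    written <<- c(written, name)
  }
  emit(timecourse, "fractions.tsv")
  emit(cluster_summary, "cluster_summary.tsv")
  emit(tests, "tests.tsv")
  emit(correlations, "correlations.tsv")

  manifest <- list(
    format = "subpopdyn-manifest", version = 1L,
    package_version = as.character(packageVersion("subpopdyn")),
    seed = seed,
    config_sha = if (!is.null(config_path) && file.exists(config_path))
      unname(tools::md5sum(config_path)) else NA_character_,
    files = as.list(setNames(
      vapply(written, function(f) unname(tools::md5sum(file.path(dir, f))),
             character(1)),
      written))
  )
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(mp)
}

#' Per-cluster feature summary table
#'
#' Means and SDs of every feature per phenotype, the table behind the
#' cluster-characterization bar panels.
#'
#' @param features Feature table.
#' @param assignments Per-event labels.
#' @param columns Feature columns to summarize (default: all standard
#'   features present).
#' @return Data.frame with one row per (label, feature).
#' @export
cluster_feature_summary <- function(features, assignments,
                                    columns = NULL) {
  df <- as.data.frame(features)
  if (is.null(columns))
    columns <- intersect(FEATURE_COLUMNS, names(df))
  labels <- sort(unique(assignments))
  rows <- list()
  for (l in labels) for (cn in columns) {
    v <- df[[cn]][assignments == l]
    rows[[length(rows) + 1L]] <- data.frame(
      label = l, feature = cn, n = length(v), mean = mean(v), sd = sd(v),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Run the full subpopulation analysis pipeline
#'
#' Executes the five framework steps on a synthetic configuration:
#' (I) feature generation (or extraction), (II) merge of the training
#' treatments, (III-IV) model search over candidate feature sets and
#' cluster numbers with the soundness criteria, (V) classification of all
#' treatments with the frozen selected model and subpopulation
#' time-course computation; then statistical characterization and report
#' export. Every stage is deterministic given the seed.
#'
#' @param config A [synthetic_config()], or a path to its YAML file.
#' @param out_dir Output directory for the report bundle.
#' @param training_treatments Treatments merged for model fitting; the
#'   remaining treatments are classified with the frozen model (default:
#'   the first two).
#' @param feature_combos Candidate feature combinations for the model
#'   search.
#' @param k_values Candidate cluster numbers.
#' @param params Base [cluster_params()].
#' @param seed Optional override of the config seed.
#' @return List with `search`, `model`, `timecourse`, `regions`,
#'   `correlations`, `tests`, `report_dir`.
#' @export
run_pipeline <- function(config, out_dir,
                         training_treatments = NULL,
                         feature_combos = list(
                           "mean_pixel_nuc_cyto",
                           c("mean_pixel_nuc_cyto", "concentration_cell")),
                         k_values = c(2L, 3L, 4L),
                         params = cluster_params(),
                         seed = NULL) {
  config_path <- NULL
  if (is.character(config)) {
    config_path <- config
    config <- read_synthetic_config(config)
  }
  if (!is.null(seed)) {
    config$seed <- as.integer(seed)
    params$seed <- as.integer(seed)
  }
  all_trts <- vapply(config$trajectories, `[[`, character(1), "treatment")
  if (is.null(training_treatments))
    training_treatments <- head(all_trts, 2L)

  message("stage 1/5: generating single-cell features")
  full <- generate_timecourse(config)
  train <- full[full$treatment %in% training_treatments, ]

  message("stage 2/5: merging training conditions")
  merged <- merge_experiments(list(train), seed = config$seed)

  message("stage 3/5: model search (clustering + criteria)")
  search <- search_models(merged, feature_combos, k_values, params = params)
  if (is.null(search$model))
    stop("no candidate model passed the soundness criteria", call. = FALSE)
  model <- search$model

  message("stage 4/5: classification and time-course decomposition")
  labels <- classify_events(model, full)
  tc <- compute_timecourse(labels, full, labels = model$label_map)
  regions <- lapply(setNames(all_trts, all_trts), function(trt)
    annotate_regions(tc, trt))

  message("stage 5/5: statistics and report export")
  correlations <- rbind(
    data.frame(x = "mean_pixel_nuc_cyto", y = "concentration_cell",
               r = single_cell_correlation(full, "mean_pixel_nuc_cyto",
                                           "concentration_cell")$r,
               n = nrow(full)),
    data.frame(x = "lamp1_max_contour_position", y = "mean_pixel_nuc_cyto",
               r = single_cell_correlation(full,
                                           "lamp1_max_contour_position",
                                           "mean_pixel_nuc_cyto")$r,
               n = nrow(full)))
  tests <- intercluster_test(full, labels, "mean_pixel_nuc_cyto",
                             seed = config$seed)
  summary_tab <- cluster_feature_summary(full, labels)
  export_report(out_dir, timecourse = tc, cluster_summary = summary_tab,
                tests = tests, correlations = correlations,
                config_path = config_path, seed = config$seed)
  list(search = search, model = model, timecourse = tc, regions = regions,
       correlations = correlations, tests = tests, report_dir = out_dir)
}
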