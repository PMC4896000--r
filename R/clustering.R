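#' Clustering parameters
#'
#' Parameter set for the density-normalized downsampling + k-means
#' clustering stage. The defaults are the standard settings of this
#' workflow: arcsinh cofactor 5, neighborhood size 5, local density
#' approximation factor 1.5, at most 50000 pooled cells, 20000 cells
#' remaining after density-dependent downsampling, k-means clustering.
#'
#' @param features Ordered character vector of feature names to cluster
#'   on.
#' @param k Number of clusters.
#' @param arcsinh_cofactor Cofactor c of the asinh(x/c) transform.
#' @param neighborhood_size Multiplier of the median nearest-neighbor
#'   distance defining the density-counting kernel radius.
#' @param density_approx_factor Multiplier applied on top of the kernel
#'   radius when approximating local density (cells within this radius of
#'   a counted cell share its density estimate in the original
#'   implementation; here it simply scales the counting radius).
#' @param max_pooled Uniform pre-subsample cap on the pooled data.
#' @param target_remaining Expected number of cells retained by
#'   density-dependent downsampling.
#' @param n_restarts k-means restarts (k-means++ initialization, best
#'   inertia kept).
#' @param seed Integer seed controlling the subsample, the downsampling
#'   draws and the k-means initializations.
#' @return A `cluster_params` list.
#' @export
cluster_params <- function(features = "mean_pixel_nuc_cyto", k = 3L,
                           arcsinh_cofactor = 5,
                           neighborhood_size = 5,
                           density_approx_factor = 1.5,
                           max_pooled = 50000L,
                           target_remaining = 20000L,
                           n_restarts = 10L, seed = 1L) {
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  if (arcsinh_cofactor <= 0) stop("cofactor must be positive", call. = FALSE)
  if (target_remaining > max_pooled)
    stop("target_remaining must not exceed max_pooled", call. = FALSE)
  structure(list(features = features, k = as.integer(k),
                 arcsinh_cofactor = arcsinh_cofactor,
                 neighborhood_size = neighborhood_size,
                 density_approx_factor = density_approx_factor,
                 max_pooled = as.integer(max_pooled),
                 target_remaining = as.integer(target_remaining),
                 n_restarts = as.integer(n_restarts),
                 seed = as.integer(seed)),
            class = "cluster_params")
}

#' Variance-stabilizing arcsinh transform
#'
#' `asinh(value / cofactor)`, the standard cytometry transform; strictly
#' increasing and defined for negative inputs.
#'
#' @param value Numeric vector or matrix.
#' @param cofactor Positive scale parameter.
#' @return Transformed values.
#' @export
arcsinh_transform <- function(value, cofactor = 5) {
  if (cofactor <= 0) stop("cofactor must be positive", call. = FALSE)
  asinh(value / cofactor)
}

#' Local density of points in transformed feature space
#'
#' Density of point i is the number of points (self included, so densities
#' are at least 1) within Euclidean distance r, where
#' `r = neighborhood_size * density_approx_factor * m` and m is the median
#' nearest-neighbor distance over a seeded random subsample of at most
#' 2000 points. When all points are identical the median neighbor
#' distance is infinite and every density equals n.
#'
#' @param points Numeric matrix (n x d) of transformed features.
#' @param params A [cluster_params()].
#' @return Integer vector of densities, length n.
#' @export
local_density <- function(points, params = cluster_params()) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 2) stop("need at least 2 points", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(params$seed)
  sub <- if (n > 2000) points[sample.int(n, 2000), , drop = FALSE]
         else points
  med <- median(.nn_dist(sub, points))
  if (!is.finite(med))
    return(rep.int(n, n))
  r <- params$neighborhood_size * params$density_approx_factor * med
  .radius_count(points, r) + 1L
}

#' Density-dependent downsampling
#'
#' Each point is kept independently with probability
#' `min(1, TD / density_i)` where the target density TD is set by
#' bisection so that the expected retained count equals
#' `min(target_remaining, n)`. This flattens the density landscape and
#' protects rare, low-density subpopulations from being swamped. When the
#' pool exceeds `max_pooled`, a seeded uniform pre-subsample is applied
#' first.
#'
#' @param points Numeric matrix of transformed features.
#' @param densities Densities from [local_density()] on these points (or
#'   NULL to compute them).
#' @param params A [cluster_params()].
#' @return Sorted integer vector of retained row indices (into the
#'   original `points`).
#' @export
density_downsample <- function(points, densities = NULL,
                               params = cluster_params()) {
  points <- as.matrix(points)
  n0 <- nrow(points)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(params$seed + 1L)
  pool <- seq_len(n0)
  if (n0 > params$max_pooled) {
    pool <- sort(sample.int(n0, params$max_pooled))
    points <- points[pool, , drop = FALSE]
    densities <- NULL
  }
  n <- nrow(points)
  if (is.null(densities)) densities <- local_density(points, params)
  if (params$target_remaining >= n) return(pool)

  expected <- function(td) sum(pmin(1, td / densities))
  lo <- 0; hi <- max(densities)
  for (i in 1:100) {
    mid <- (lo + hi) / 2
    if (expected(mid) < params$target_remaining) lo <- mid else hi <- mid
  }
  td <- hi
  keep <- runif(n) < pmin(1, td / densities)
  pool[keep]
}

# k-means++ seeding (Arthur & Vassilvitskii): first center uniform, then
# each next center drawn with probability proportional to squared distance
# to the nearest chosen center.
.kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  i <- sample.int(n, 1)
  centers[1, ] <- x[i, ]
  d2 <- rowSums((x - matrix(centers[1, ], n, ncol(x), byrow = TRUE))^2)
  if (k > 1) for (j in 2:k) {
    if (sum(d2) <= 0) i <- sample.int(n, 1)
    else i <- sample.int(n, 1, prob = d2)
    centers[j, ] <- x[i, ]
    d2 <- pmin(d2, rowSums((x - matrix(centers[j, ], n, ncol(x),
                                       byrow = TRUE))^2))
  }
  centers
}

# Nearest-centroid assignment in transformed space; ties broken toward the
# lowest centroid index (max.col with ties.method="first" on negated
# distances).
.assign_nearest <- function(x, centers) {
  n <- nrow(x); k <- nrow(centers)
  d2 <- matrix(0, n, k)
  for (j in seq_len(k)) {
    d2[, j] <- rowSums((x - matrix(centers[j, ], n, ncol(x),
                                   byrow = TRUE))^2)
  }
  max.col(-d2, ties.method = "first")
}

#' Fit the density-normalized clustering model
#'
#' Pipeline: select the clustering features, arcsinh-transform, estimate
#' local densities, density-downsample, run k-means (k-means++
#' initialization, `n_restarts` restarts, best within-cluster sum of
#' squares kept) on the retained cells, then assign every event - retained
#' or not - to its nearest centroid in transformed space. Cluster indices
#' are reordered by ascending centroid position along the first clustering
#' feature so that the model is invariant to restart ordering.
#'
#' @param events Feature table (data.frame) containing the clustering
#'   features.
#' @param params A [cluster_params()].
#' @return A `cluster_model`: list with `params`, `centroids` (k x d,
#'   transformed space), `label_map` (cluster index -> label; generic
#'   C1..Ck until [label_clusters()] is applied), `training_summary`
#'   (per-cluster counts and per-feature raw-space means/SDs) and
#'   `assignments` (training cluster index per event).
#' @export
fit_cluster_model <- function(events, params = cluster_params()) {
  miss <- setdiff(params$features, names(events))
  if (length(miss))
    stop("feature(s) not in table: ", paste(miss, collapse = ", "),
         call. = FALSE)
  raw <- as.matrix(as.data.frame(events)[, params$features, drop = FALSE])
  bad <- which(!stats::complete.cases(raw) | rowSums(!is.finite(raw)) > 0)
  if (length(bad))
    stop("non-finite feature values in rows: ",
         paste(head(bad, 10), collapse = ", "),
         if (length(bad) > 10) " ..." else "", call. = FALSE)
  x <- arcsinh_transform(raw, params$arcsinh_cofactor)

  keep <- density_downsample(x, params = params)
  xs <- x[keep, , drop = FALSE]
  if (nrow(unique(xs)) < params$k)
    stop(sprintf("fewer than k = %d distinct points after downsampling",
                 params$k), call. = FALSE)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(params$seed + 2L)
  if (params$k == 1L) {
    centers <- matrix(colMeans(xs), 1L, ncol(xs))
  } else {
    best <- NULL
    for (r in seq_len(params$n_restarts)) {
      init <- .kmeanspp_init(xs, params$k)
      km <- suppressWarnings(
        stats::kmeans(xs, centers = init, iter.max = 100L,
                      algorithm = "Lloyd"))
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
    centers <- best$centers
  }
  ord <- order(centers[, 1])
  centers <- centers[ord, , drop = FALSE]
  dimnames(centers) <- list(NULL, params$features)

  assignments <- .assign_nearest(x, centers)
  model <- structure(list(
    params = params,
    centroids = centers,
    label_map = paste0("C", seq_len(params$k)),
    training_summary = .training_summary(events, assignments, params$k),
    assignments = assignments
  ), class = "cluster_model")
  model
}

# Per-cluster counts and raw-space feature means/SDs over all numeric
# feature columns present.
.training_summary <- function(events, assignments, k) {
  df <- as.data.frame(events)
  num_cols <- names(df)[vapply(df, is.numeric, logical(1))]
  num_cols <- setdiff(num_cols, c("time_h", "replicate"))
  lapply(seq_len(k), function(j) {
    idx <- assignments == j
    list(n = sum(idx),
         means = vapply(num_cols, function(cn) mean(df[[cn]][idx]),
                        numeric(1)),
         sds = vapply(num_cols, function(cn) sd(df[[cn]][idx]),
                      numeric(1)))
  })
}

#' Assign activity-phenotype labels to clusters
#'
#' For a three-cluster model, clusters are ordered by ascending training
#' mean of the ranking feature (default: the nuclear/cytoplasmic pixel
#' ratio) and labeled Inactive < Medium < Active; the Active cluster has
#' the highest nuclear localization. For any other k, generic labels
#' C1..Ck are kept and a warning is raised. Ties in the ranking mean are
#' broken by cluster size, larger first.
#'
#' @param model A `cluster_model`.
#' @param ranking_feature Feature name used to order clusters.
#' @return The model with `label_map` filled in.
#' @export
label_clusters <- function(model, ranking_feature = "mean_pixel_nuc_cyto") {
  stopifnot(inherits(model, "cluster_model"))
  k <- model$params$k
  means <- vapply(model$training_summary, function(s) {
    if (!ranking_feature %in% names(s$means))
      stop("ranking feature not in training summary: ", ranking_feature,
           call. = FALSE)
    s$means[[ranking_feature]]
  }, numeric(1))
  sizes <- vapply(model$training_summary, `[[`, numeric(1), "n")
  if (k != 3L) {
    warning(sprintf(
      "phenotype labels require k = 3 (got k = %d); keeping generic labels",
      k))
    model$label_map <- paste0("C", seq_len(k))
    return(model)
  }
  ord <- order(means, -sizes)
  labels <- character(k)
  labels[ord] <- PHENOTYPE_LABELS
  model$label_map <- labels
  model
}

#' Classify events with a fitted model
#'
#' Applies the stored arcsinh cofactor and centroids: nearest centroid in
#' transformed space, label via the model's label map. No refitting takes
#' place, so a model trained on reference treatments can be transferred
#' unchanged to new conditions.
#'
#' @param model A `cluster_model`.
#' @param events Feature table containing the model's features.
#' @return Character vector of labels, one per event, with the cluster
#'   index as the `"cluster"` attribute.
#' @export
classify_events <- function(model, events) {
  stopifnot(inherits(model, "cluster_model"))
  miss <- setdiff(model$params$features, names(events))
  if (length(miss))
    stop("feature column(s) missing: ", paste(miss, collapse = ", "),
         call. = FALSE)
  raw <- as.matrix(
    as.data.frame(events)[, model$params$features, drop = FALSE])
  x <- arcsinh_transform(raw, model$params$arcsinh_cofactor)
  idx <- .assign_nearest(x, model$centroids)
  out <- model$label_map[idx]
  attr(out, "cluster") <- idx
  out
}

#' Persist or restore a cluster model as structured text
#'
#' Models are stored as JSON with a format version field: parameters,
#' centroids, label map and training summary.
#'
#' @param model A `cluster_model`.
#' @param path File path.
#' @return `read_cluster_model` returns a `cluster_model` (without the
#'   training assignments, which are not persisted).
#' @export
write_cluster_model <- function(model, path) {
  stopifnot(inherits(model, "cluster_model"))
  out <- list(
    format = "subpopdyn-cluster-model",
    version = 1L,
    params = unclass(model$params),
    centroids = model$centroids,
    label_map = model$label_map,
    training_summary = model$training_summary
  )
  jsonlite::write_json(out, path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_cluster_model
#' @export
read_cluster_model <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(raw$format, "subpopdyn-cluster-model"))
    stop("not a cluster-model file: ", path, call. = FALSE)
  params <- do.call(cluster_params, raw$params)
  ts <- lapply(seq_len(params$k), function(j) {
    s <- if (is.data.frame(raw$training_summary))
      as.list(raw$training_summary[j, ]) else raw$training_summary[[j]]
    list(n = s$n, means = unlist(s$means), sds = unlist(s$sds))
  })
  centroids <- as.matrix(raw$centroids)
  dimnames(centroids) <- list(NULL, params$features)
  structure(list(params = params,
                 centroids = centroids,
                 label_map = raw$label_map,
                 training_summary = ts,
                 assignments = NULL),
            class = "cluster_model")
}
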