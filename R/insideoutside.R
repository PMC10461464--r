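#' Configuration of the insideOutside classifier
#'
#' Bundles every tunable of the classifier. The defaults reproduce the
#' published algorithm: bivariate decision space
#' \eqn{[\log_{10}(m + \epsilon), v]} with \eqn{\epsilon = 0.01}, and Ward
#' hierarchical clustering cut at two groups.
#'
#' @param epsilon Small positive offset added to the unit-scaled minimum
#'   distance before the log10 transform; must lie in (0, 1). Default 0.01.
#' @param transform `"log10"` (default) or `"raw"` (use the scaled minimum
#'   distance untransformed).
#' @param clustering One of `"hierarchical"` (Ward linkage, Euclidean
#'   distance, tree cut at 2 clusters; the published default), `"kmeans"`,
#'   `"spectral"`, or `"dbscan"`.
#' @param feature_mode `"bivariate"` (default), `"m-only"`, or `"v-only"`;
#'   the univariate modes exist for feature-ablation experiments.
#' @param dbscan_eps,dbscan_min_pts DBSCAN neighbourhood radius (in scaled
#'   feature units) and core-point threshold; only used when
#'   `clustering = "dbscan"`. Non-core ("noise") points are assigned to the
#'   nearest cluster centroid.
#' @param seed Optional integer seed for the stochastic clusterers
#'   (k-means, spectral); the default hierarchical route is deterministic.
#' @return A list of class `io_config`.
#' @export
io_config <- function(epsilon = 0.01,
                      transform = c("log10", "raw"),
                      clustering = c("hierarchical", "kmeans", "spectral", "dbscan"),
                      feature_mode = c("bivariate", "m-only", "v-only"),
                      dbscan_eps = 0.1,
                      dbscan_min_pts = 4L,
                      seed = NULL) {
  transform <- match.arg(transform)
  clustering <- match.arg(clustering)
  feature_mode <- match.arg(feature_mode)
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon <= 0 || epsilon >= 1)
    stop("`epsilon` must lie in (0, 1)")
  structure(
    list(epsilon = epsilon, transform = transform, clustering = clustering,
         feature_mode = feature_mode, dbscan_eps = dbscan_eps,
         dbscan_min_pts = as.integer(dbscan_min_pts), seed = seed),
    class = "io_config"
  )
}

#' Per-point decision-space features
#'
#' Computes, for every point of a cloud, the minimum `m` and variance `v` of
#' its distances to all triangular faces of the cloud's own convex hull, and
#' maps them to the classifier's decision space:
#' \enumerate{
#'   \item min-max scale `m` and `v` across points to \[0, 1\];
#'   \item (when `transform = "log10"`) replace the scaled `m` by
#'     \eqn{\log_{10}(m_{01} + \epsilon)} and min-max rescale the result to
#'     \[0, 1\] so that both axes are commensurate for Euclidean clustering.
#' }
#' Hull vertices have `m = 0`, so before the final rescale their transformed
#' feature equals \eqn{\log_{10}(\epsilon)} (-2 at the default
#' \eqn{\epsilon = 0.01}).
#'
#' @param points An \eqn{n \times 3} coordinate matrix, \eqn{n \ge 5}.
#' @param config An [io_config()].
#' @return An object of class `io_features`: a list with `features` (the
#'   \eqn{n \times k} matrix handed to the clusterer, entries in \[0, 1\]),
#'   `f1` / `f2` (the transformed minimum-distance and scaled variance
#'   features; `f1` is `NULL` in `"v-only"` mode and `f2` in `"m-only"`),
#'   `f1_pre` (the transformed feature before the final rescale), `m`, `v`
#'   (the raw per-point summaries), `hull`, and `config`.
#' @export
compute_features <- function(points, config = io_config()) {
  stopifnot(inherits(config, "io_config"))
  coords <- as_coords(points, n_min = 5L)
  hull <- build_hull(coords)
  prof <- profile_cloud(coords, hull)

  m01 <- rescale01(prof$m, what = "minimum distance m")
  f2 <- rescale01(prof$v, what = "variance of distances v")
  if (config$transform == "log10") {
    f1_pre <- log10(m01 + config$epsilon)
    f1 <- rescale01(f1_pre, what = "log-transformed minimum distance")
  } else {
    f1_pre <- m01
    f1 <- m01
  }
  features <- switch(config$feature_mode,
    "bivariate" = cbind(f1 = f1, f2 = f2),
    "m-only"    = cbind(f1 = f1),
    "v-only"    = cbind(f2 = f2)
  )
  structure(
    list(features = features,
         f1 = if (config$feature_mode != "v-only") f1 else NULL,
         f2 = if (config$feature_mode != "m-only") f2 else NULL,
         f1_pre = f1_pre, m = prof$m, v = prof$v,
         hull = hull, config = config),
    class = "io_features"
  )
}

#' Split decision-space features into two groups
#'
#' Unsupervised two-group clustering of the feature matrix. The published
#' algorithm uses hierarchical clustering with Ward linkage on Euclidean
#' distances (`hclust(method = "ward.D2")`), cut at exactly two clusters;
#' k-means, spectral clustering and DBSCAN are provided for method
#' comparisons.
#'
#' @param features An `io_features` object or a numeric feature matrix.
#' @param method Clustering method; defaults to the method recorded in the
#'   feature object's config (or `"hierarchical"` for a bare matrix).
#' @param config An [io_config()] supplying seeds and DBSCAN parameters when
#'   `features` is a bare matrix.
#' @return An integer vector of group ids (1 or 2), one per point.
#' @export
cluster_features <- function(features, method = NULL, config = NULL) {
  if (inherits(features, "io_features")) {
    config <- config %||% features$config
    X <- features$features
  } else {
    X <- as.matrix(features)
    config <- config %||% io_config()
  }
  method <- method %||% config$clustering
  method <- match.arg(method, c("hierarchical", "kmeans", "spectral", "dbscan"))
  if (nrow(X) < 2L || nrow(unique(X)) < 2L)
    stop("cannot split: fewer than 2 distinct feature rows")

  groups <- switch(method,
    hierarchical = cutree(hclust(dist(X), method = "ward.D2"), k = 2L),
    kmeans = with_seed(config$seed %||% 1L,
                       kmeans(X, centers = 2L, nstart = 10L)$cluster),
    spectral = with_seed(config$seed %||% 1L, {
      cl <- kernlab::specc(X, centers = 2L)
      as.integer(cl@.Data)
    }),
    dbscan = cluster_dbscan(X, config$dbscan_eps, config$dbscan_min_pts)
  )
  as.integer(groups)
}

# Plain-vanilla DBSCAN on a feature matrix (density-based clustering with
# Euclidean eps-neighbourhoods). Noise points are attached to the nearest
# cluster centroid; anything other than exactly two clusters is an error,
# since the classifier needs a binary split.
cluster_dbscan <- function(X, eps, min_pts) {
  n <- nrow(X)
  D <- as.matrix(dist(X))
  nb <- lapply(seq_len(n), function(i) which(D[i, ] <= eps))
  core <- vapply(nb, length, integer(1L)) >= min_pts
  cl <- integer(n)
  current <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || cl[i] != 0L) next
    current <- current + 1L
    queue <- i
    cl[i] <- current
    while (length(queue)) {
      j <- queue[[1L]]
      queue <- queue[-1L]
      for (k in nb[[j]]) {
        if (cl[k] == 0L) {
          cl[k] <- current
          if (core[k]) queue <- c(queue, k)
        }
      }
    }
  }
  if (current != 2L)
    stop(sprintf("clustering failed, adjust parameters: DBSCAN found %d cluster(s), need 2", current))
  noise <- which(cl == 0L)
  if (length(noise)) {
    cent <- rbind(colMeans(X[cl == 1L, , drop = FALSE]),
                  colMeans(X[cl == 2L, , drop = FALSE]))
    for (i in noise) {
      d2 <- rowSums((cent - matrix(X[i, ], 2L, ncol(X), byrow = TRUE))^2)
      cl[i] <- which.min(d2)
    }
  }
  cl
}

#' Label the two groups as inside and outside
#'
#' Converts anonymous cluster ids into inside/outside labels: interior
#' points sit far from every hull face, so the group with the larger mean
#' transformed-minimum-distance feature is labelled inside (0) and the other
#' outside (1). In `"v-only"` mode the variance feature is used instead,
#' with the smaller mean variance marking the inside group. An exact tie in
#' means is broken deterministically: the group containing the point of
#' globally maximal `f1` (minimal `f2` for `"v-only"`) is inside.
#'
#' @param groups Integer vector of group ids (exactly two distinct values).
#' @param features The `io_features` the groups were computed from.
#' @return An object of class `io_classification`: a list with `labels`
#'   (integer vector, 0 = inside, 1 = outside), `features`, `groups`, and
#'   `method`.
#' @export
assign_inside_outside <- function(groups, features) {
  stopifnot(inherits(features, "io_features"))
  ids <- sort(unique(groups))
  if (length(ids) != 2L)
    stop("exactly 2 groups are required")
  if (is.null(features$f1)) {
    score <- -features$f2   # low variance marks the interior
  } else {
    score <- features$f1    # high minimum distance marks the interior
  }
  means <- vapply(ids, function(g) mean(score[groups == g]), numeric(1L))
  if (means[1L] == means[2L]) {
    inside_id <- groups[which.max(score)]
  } else {
    inside_id <- ids[which.max(means)]
  }
  labels <- ifelse(groups == inside_id, 0L, 1L)
  structure(
    list(labels = as.integer(labels), features = features,
         groups = as.integer(groups),
         method = sprintf("insideOutside (%s, %s, %s)",
                          features$config$transform,
                          features$config$feature_mode,
                          features$config$clustering)),
    class = "io_classification"
  )
}

#' Classify interior and exterior points of a 3D point cloud
#'
#' The insideOutside classifier. Takes an \eqn{n \times 3} matrix of
#' Cartesian points and returns a bit vector labelling each point inside (0)
#' or outside (1), by composing [compute_features()],
#' [cluster_features()] and [assign_inside_outside()]. With the default
#' configuration this is the published algorithm: distances from each point
#' to every triangular face of the cloud's convex hull, per-point minimum
#' and variance scaled to \[0, 1\], decision space
#' \eqn{[\log_{10}(m + 0.01), v]}, Ward hierarchical clustering into two
#' groups. Labels are invariant under rigid motion and uniform scaling of
#' the cloud.
#'
#' @param points An \eqn{n \times 3} coordinate matrix (or anything with a
#'   `$points` matrix, e.g. the result of [make_test_shape()]),
#'   \eqn{n \ge 5}.
#' @param config An [io_config()].
#' @return An `io_classification` (see [assign_inside_outside()]), with the
#'   input coordinates attached as `$points`.
#' @examples
#' shape <- make_test_shape(shape_spec(inner_radius = 0.3, seed = 1))
#' res <- inside_outside(shape)
#' table(truth = shape$truth, predicted = res$labels)
#' @export
inside_outside <- function(points, config = io_config()) {
  coords <- as_coords(points, n_min = 5L)
  feats <- compute_features(coords, config)
  groups <- cluster_features(feats)
  res <- assign_inside_outside(groups, feats)
  res$points <- coords
  res
}

#' @export
print.io_classification <- function(x, ...) {
  cat(sprintf("%s: %d points, %d inside (0) / %d outside (1)\n",
              x$method, length(x$labels),
              sum(x$labels == 0L), sum(x$labels == 1L)))
  invisible(x)
}
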