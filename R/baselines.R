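#' RANSAC configuration for robust ellipsoid fitting
#'
#' @param n_iterations Number of random minimal-sample fits (default 500).
#' @param sample_size Points per minimal sample; a general quadric has 9
#'   degrees of freedom so this must be at least 9.
#' @param inlier_tolerance Inlier threshold on the gradient-normalised
#'   algebraic residual (approximate geometric distance, in the cloud's
#'   length units). `NULL` (default) means 0.05 times the cloud diameter.
#' @param seed Optional integer seed; fixing it makes the fit bit-identical
#'   across runs.
#' @return A list of class `ransac_config`.
#' @export
ransac_config <- function(n_iterations = 500L, sample_size = 9L,
                          inlier_tolerance = NULL, seed = NULL) {
  if (sample_size < 9L) stop("`sample_size` must be at least 9")
  if (n_iterations < 1L) stop("`n_iterations` must be at least 1")
  structure(
    list(n_iterations = as.integer(n_iterations),
         sample_size = as.integer(sample_size),
         inlier_tolerance = inlier_tolerance, seed = seed),
    class = "ransac_config"
  )
}

# Least-squares fit of the general quadric
#   x'Qx + 2 b'x = 1
# returning list(Q, b, coef). Rows of the design matrix are
# [x^2, y^2, z^2, 2xy, 2xz, 2yz, 2x, 2y, 2z].
fit_quadric <- function(coords) {
  x <- coords[, 1L]; y <- coords[, 2L]; z <- coords[, 3L]
  M <- cbind(x^2, y^2, z^2, 2 * x * y, 2 * x * z, 2 * y * z, 2 * x, 2 * y, 2 * z)
  coef <- qr.solve(M, rep(1, nrow(coords)))
  Q <- matrix(c(coef[1L], coef[4L], coef[5L],
                coef[4L], coef[2L], coef[6L],
                coef[5L], coef[6L], coef[3L]), 3L, 3L)
  list(Q = Q, b = coef[7:9], coef = coef)
}

# Decompose a fitted quadric into centre / orientation / radii, or error if
# the quadric is not an ellipsoid.
quadric_to_ellipsoid <- function(fit) {
  Q <- fit$Q
  if (abs(det(Q)) < 1e-300) stop("fit is not an ellipsoid")
  centre <- drop(-solve(Q, fit$b))
  k <- 1 + drop(crossprod(centre, Q %*% centre))
  eig <- eigen(Q, symmetric = TRUE)
  # the "= 1" normalisation flips the sign of (Q, k) when the origin lies
  # outside the surface; an ellipsoid needs all ratios k/lambda positive
  ratios <- k / eig$values
  if (any(!is.finite(ratios)) || any(ratios <= 0))
    stop("fit is not an ellipsoid: quadratic form is not positive definite")
  radii <- sqrt(ratios)
  ord <- order(radii, decreasing = TRUE)
  radii <- radii[ord]
  orientation <- eig$vectors[, ord, drop = FALSE]
  if (det(orientation) < 0) orientation[, 3L] <- -orientation[, 3L]
  structure(list(centre = centre, orientation = orientation, radii = radii),
            class = "ellipsoid")
}

#' @export
print.ellipsoid <- function(x, ...) {
  cat(sprintf("Ellipsoid: centre (%.4g, %.4g, %.4g), radii (%.4g, %.4g, %.4g)\n",
              x$centre[1], x$centre[2], x$centre[3],
              x$radii[1], x$radii[2], x$radii[3]))
  invisible(x)
}

#' Naive least-squares ellipsoid fit
#'
#' Fits a general quadric surface to the cloud by linear least squares and
#' accepts the first fit, i.e. no consensus iteration. The quadric is
#' decomposed into centre, orthonormal orientation axes (det +1) and the
#' three semi-axis radii (sorted decreasing); a fit whose quadratic form is
#' not positive definite is rejected.
#'
#' @param points An \eqn{n \times 3} coordinate matrix with \eqn{n \ge 9}
#'   (a general quadric has 9 degrees of freedom).
#' @return An object of class `ellipsoid` with fields `centre`,
#'   `orientation` and `radii`.
#' @export
fit_ellipsoid_naive <- function(points) {
  coords <- as_coords(points, n_min = 1L)
  if (nrow(coords) < 9L)
    stop("underdetermined: ellipsoid fitting needs at least 9 points")
  quadric_to_ellipsoid(fit_quadric(coords))
}

# Gradient-normalised algebraic residual |q(x)| / ||grad q(x)||: a
# first-order approximation to the geometric distance from each point to
# the quadric surface, in length units.
quadric_residuals <- function(coords, fit) {
  qx <- coords %*% fit$Q
  val <- rowSums(qx * coords) + 2 * drop(coords %*% fit$b) - 1
  grad <- 2 * (qx + matrix(fit$b, nrow(coords), 3L, byrow = TRUE))
  gn <- sqrt(rowSums(grad^2))
  abs(val) / pmax(gn, .Machine$double.eps)
}

#' RANSAC ellipsoid fit
#'
#' Robustly fits an ellipsoid by random sample consensus: repeatedly fit on
#' a random minimal sample, count the points whose (gradient-normalised)
#' algebraic residual is within the inlier tolerance, and refit on the
#' largest consensus set found. With outlier-free data the consensus set is
#' the whole cloud and the result coincides with [fit_ellipsoid_naive()].
#'
#' @param points An \eqn{n \times 3} coordinate matrix.
#' @param config A [ransac_config()].
#' @return An `ellipsoid` with two extra fields: `inliers` (indices of the
#'   final consensus set) and `n_valid_iterations` (iterations whose minimal
#'   sample produced an ellipsoidal fit).
#' @export
fit_ellipsoid_ransac <- function(points, config = ransac_config()) {
  stopifnot(inherits(config, "ransac_config"))
  coords <- as_coords(points, n_min = 1L)
  n <- nrow(coords)
  if (n < config$sample_size)
    stop(sprintf("underdetermined: need at least %d points", config$sample_size))
  tol <- config$inlier_tolerance %||% (0.05 * cloud_diameter(coords))

  with_seed(config$seed, {
    best_inliers <- integer(0L)
    n_valid <- 0L
    for (it in seq_len(config$n_iterations)) {
      idx <- sample.int(n, config$sample_size)
      fit <- tryCatch({
        f <- fit_quadric(coords[idx, , drop = FALSE])
        quadric_to_ellipsoid(f)  # validate ellipsoidal-ness
        f
      }, error = function(e) NULL)
      if (is.null(fit)) next
      n_valid <- n_valid + 1L
      inl <- which(quadric_residuals(coords, fit) <= tol)
      if (length(inl) > length(best_inliers)) best_inliers <- inl
    }
    if (n_valid == 0L || length(best_inliers) < 9L)
      stop("RANSAC failed: no iteration produced an ellipsoidal fit")
    e <- quadric_to_ellipsoid(fit_quadric(coords[best_inliers, , drop = FALSE]))
    e$inliers <- best_inliers
    e$n_valid_iterations <- n_valid
    e
  })
}

#' Closest point on an ellipsoid surface
#'
#' Exact closest point via 1D root-finding on the Lagrange-multiplier
#' equation: in the ellipsoid's axis frame the closest surface point to `y`
#' is \eqn{s_i = a_i^2 y_i / (a_i^2 + t)} where `t` solves
#' \eqn{\sum_i a_i^2 y_i^2 / (a_i^2 + t)^2 = 1}. The function is strictly
#' decreasing in `t`, so the root is bracketed and found with [uniroot()]
#' (tolerance 1e-12). If root-finding fails the point is radially projected
#' onto the surface, with a warning.
#'
#' @param p A 3D point.
#' @param e An `ellipsoid`.
#' @return The closest point on the surface of `e`, in world coordinates.
#' @export
ellipsoid_closest_point <- function(p, e) {
  stopifnot(inherits(e, "ellipsoid"))
  y <- drop(crossprod(e$orientation, as.numeric(p) - e$centre))
  a2 <- e$radii^2
  tiny <- 1e-14 * max(e$radii)
  active <- abs(y) > tiny
  if (!any(active)) {
    # centre of the ellipsoid: every direction ties; pick the shortest axis
    s <- c(0, 0, 0)
    s[which.min(e$radii)] <- e$radii[which.min(e$radii)]
    return(drop(e$orientation %*% s) + e$centre)
  }
  fn <- function(t) sum(a2[active] * y[active]^2 / (a2[active] + t)^2) - 1
  lower <- -min(a2[active])
  lower <- lower + 1e-12 * (abs(lower) + 1)
  upper <- sqrt(sum(a2 * y^2))  # guarantees fn(upper) <= 0
  s <- tryCatch({
    while (fn(lower) <= 0) lower <- lower - 0.5 * (lower + min(a2[active]))
    t_star <- uniroot(fn, c(lower, upper), tol = 1e-12, maxiter = 100L)$root
    a2 * y / (a2 + t_star)
  }, error = function(err) {
    warning("closest-point root-finding did not converge; falling back to radial projection")
    y / sqrt(sum(y^2 / a2))
  })
  drop(e$orientation %*% s) + e$centre
}

#' Ellipsoidal inside/outside classification (the 0.95 distance rule)
#'
#' Classifies each point against a fitted ellipsoid: a point is labelled
#' outside (1) if the distance from the ellipsoid's centre to the point
#' exceeds `threshold` times the distance from the centre to the surface
#' point closest to it; points exactly at the threshold are inside. When the
#' ellipsoid is a sphere this reduces to a radius test.
#'
#' @param points An \eqn{n \times 3} coordinate matrix.
#' @param e An `ellipsoid` (e.g. from [fit_ellipsoid_naive()] or
#'   [fit_ellipsoid_ransac()]); `NULL` fits one to `points` first.
#' @param threshold The distance-ratio threshold (default 0.95).
#' @param method When `e` is `NULL`, which fit to use: `"naive"` or
#'   `"ransac"`.
#' @param config A [ransac_config()] for the `"ransac"` route.
#' @return An `io_classification` with labels 0 (inside) / 1 (outside), the
#'   fitted `ellipsoid`, and the input `points`.
#' @export
classify_ellipsoid <- function(points, e = NULL, threshold = 0.95,
                               method = c("naive", "ransac"),
                               config = ransac_config()) {
  method <- match.arg(method)
  coords <- as_coords(points, n_min = 1L)
  if (is.null(e)) {
    e <- switch(method,
                naive = fit_ellipsoid_naive(coords),
                ransac = fit_ellipsoid_ransac(coords, config))
    label <- switch(method, naive = "Naive Ellipsoidal", ransac = "RANSAC Ellipsoidal")
  } else {
    label <- "Ellipsoidal (user-supplied fit)"
  }
  stopifnot(inherits(e, "ellipsoid"))
  labels <- vapply(seq_len(nrow(coords)), function(i) {
    p <- coords[i, ]
    d_point <- sqrt(sum((p - e$centre)^2))
    if (d_point == 0) return(0L)
    s <- ellipsoid_closest_point(p, e)
    d_surface <- sqrt(sum((s - e$centre)^2))
    # float-safe "exceeds": exact threshold equality stays inside
    if (d_point > threshold * d_surface * (1 + 1e-9)) 1L else 0L
  }, integer(1L))
  structure(
    list(labels = labels, ellipsoid = e, threshold = threshold,
         method = label, points = coords),
    class = "io_classification"
  )
}

#' Convex-hull inside/outside classification
#'
#' The boundary-membership rule: a point is outside (1) exactly when it is a
#' vertex of the cloud's convex hull, and inside (0) otherwise.
#'
#' @param points An \eqn{n \times 3} coordinate matrix, \eqn{n \ge 5}.
#' @return An `io_classification` with the `triangulated_hull` attached.
#' @examples
#' tetra <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
#' classify_convex_hull(rbind(tetra, c(0, 0, 0)))$labels  # 1 1 1 1 0
#' @export
classify_convex_hull <- function(points) {
  coords <- as_coords(points, n_min = 5L)
  hull <- build_hull(coords)
  labels <- as.integer(seq_len(nrow(coords)) %in% hull$vertices)
  structure(
    list(labels = labels, hull = hull, method = "Convex Hull", points = coords),
    class = "io_classification"
  )
}
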