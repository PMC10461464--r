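#' Specification of a synthetic embryo-like test shape
#'
#' The defaults emulate the late mouse blastocyst, whose cell number is
#' roughly 100--150 with 60--70% trophectoderm: 100 "outside" points
#' uniformly distributed on the unit sphere plus 50 "inside" points
#' uniformly distributed in a concentric ball, with optional Gaussian
#' surface noise emulating local concavities.
#'
#' @param n_outside Number of surface points (default 100).
#' @param n_inside Number of interior ball points (default 50).
#' @param inner_radius Radius of the inner ball, in (0, `outer_radius`\]
#'   (default 0.5).
#' @param outer_radius Sphere radius (default 1).
#' @param noise_factor Standard deviation of the total Gaussian displacement
#'   applied to the surface points only (default 0, i.e. none), on the
#'   outer-radius scale. For the isotropic model this corresponds to a
#'   per-coordinate standard deviation of `noise_factor / sqrt(3)`.
#' @param noise_model `"isotropic"` (spherically symmetric Gaussian
#'   displacement; default) or `"radial"` (noise along the outward radial
#'   direction only).
#' @param seed Optional integer seed; fixing it makes the shape
#'   bit-reproducible.
#' @return A list of class `shape_spec`.
#' @export
shape_spec <- function(n_outside = 100L, n_inside = 50L, inner_radius = 0.5,
                       outer_radius = 1, noise_factor = 0,
                       noise_model = c("isotropic", "radial"), seed = NULL) {
  noise_model <- match.arg(noise_model)
  if (n_outside < 0L || n_inside < 0L) stop("point counts must be non-negative")
  if (inner_radius <= 0 || inner_radius > outer_radius)
    stop("`inner_radius` must lie in (0, outer_radius]")
  if (noise_factor < 0) stop("`noise_factor` must be non-negative")
  structure(
    list(n_outside = as.integer(n_outside), n_inside = as.integer(n_inside),
         inner_radius = inner_radius, outer_radius = outer_radius,
         noise_factor = noise_factor, noise_model = noise_model, seed = seed),
    class = "shape_spec"
  )
}

#' Uniform random points on a sphere
#'
#' Samples i.i.d. points uniformly on the radius-`r` sphere by normalising
#' isotropic Gaussian vectors.
#'
#' @param n Number of points.
#' @param r Radius (default 1).
#' @param seed Optional integer seed.
#' @return An \eqn{n \times 3} coordinate matrix.
#' @export
sample_sphere_uniform <- function(n, r = 1, seed = NULL) {
  stopifnot(n >= 0, r > 0)
  with_seed(seed, {
    g <- matrix(rnorm(3L * n), ncol = 3L)
    x <- r * g / sqrt(rowSums(g^2))
    colnames(x) <- c("x", "y", "z")
    x
  })
}

#' Uniform random points in a ball
#'
#' Samples i.i.d. points uniformly in the closed radius-`r` ball: uniform
#' directions with radii proportional to \eqn{U^{1/3}}.
#'
#' @inheritParams sample_sphere_uniform
#' @return An \eqn{n \times 3} coordinate matrix.
#' @export
sample_ball_uniform <- function(n, r = 1, seed = NULL) {
  stopifnot(n >= 0, r > 0)
  with_seed(seed, {
    u <- sample_sphere_uniform(n, r = 1)
    rad <- r * runif(n)^(1 / 3)
    x <- u * rad
    colnames(x) <- c("x", "y", "z")
    x
  })
}

#' Deterministic near-equidistant points on a sphere
#'
#' A Fibonacci (golden-angle) lattice: latitudes at the midpoints of `n`
#' equal-area bands, longitudes advancing by the golden angle. This gives an
#' approximately equal-area, deterministic arrangement whose minimum
#' pairwise distance is close to the hexagonal-packing estimate
#' \eqn{\sqrt{8\pi/(\sqrt{3}\,n)}\, r}. For `n = 2` the exact optimum (two
#' antipodal poles) is returned.
#'
#' @param n Number of points, at least 2.
#' @param r Radius (default 1).
#' @return An \eqn{n \times 3} coordinate matrix.
#' @export
equidistant_sphere_points <- function(n, r = 1) {
  stopifnot(r > 0)
  if (n < 2L) stop("`n` must be at least 2")
  if (n == 2L)
    return(matrix(c(0, 0, r, 0, 0, -r), ncol = 3L, byrow = TRUE,
                  dimnames = list(NULL, c("x", "y", "z"))))
  i <- seq_len(n) - 1L
  z <- 1 - (2 * i + 1) / n
  rho <- sqrt(pmax(1 - z^2, 0))
  theta <- i * pi * (3 - sqrt(5))  # golden angle
  x <- r * cbind(x = rho * cos(theta), y = rho * sin(theta), z = z)
  x
}

#' Equally spaced test points along a radius
#'
#' `n` points from the origin to the surface point `r * direction`,
#' inclusive, used to probe the minimum-distance/variance relationship along
#' a radius of a discretised sphere.
#'
#' @param n Number of points (default 50).
#' @param r Radius (default 1).
#' @param direction Direction vector (need not be unit length); default the
#'   z-axis.
#' @return An \eqn{n \times 3} coordinate matrix; consecutive points are
#'   spaced `r / (n - 1)` apart.
#' @export
test_points_along_radius <- function(n = 50L, r = 1, direction = c(0, 0, 1)) {
  stopifnot(n >= 1L, r > 0)
  direction <- as.numeric(direction)
  nrm <- sqrt(sum(direction^2))
  if (!is.finite(nrm) || nrm == 0) stop("`direction` must be a non-zero vector")
  u <- direction / nrm
  s <- if (n == 1L) 0 else seq(0, r, length.out = n)
  x <- outer(s, u)
  colnames(x) <- c("x", "y", "z")
  x
}

#' Gaussian surface noise
#'
#' Perturbs each point by an i.i.d. isotropic Gaussian displacement with
#' per-coordinate standard deviation `noise_factor` (the mean displacement
#' norm is then \eqn{\sigma\sqrt{8/\pi}}), or by a radial-only Gaussian
#' displacement when `model = "radial"`.
#'
#' @param points An \eqn{n \times 3} coordinate matrix.
#' @param noise_factor Non-negative per-coordinate standard deviation, in
#'   the cloud's length units.
#' @param seed Optional integer seed.
#' @param model `"isotropic"` (default) or `"radial"` (displacement along
#'   the direction from the cloud centroid).
#' @return The perturbed coordinate matrix.
#' @export
add_surface_noise <- function(points, noise_factor, seed = NULL,
                              model = c("isotropic", "radial")) {
  model <- match.arg(model)
  coords <- as_coords(points)
  if (noise_factor < 0) stop("`noise_factor` must be non-negative")
  if (noise_factor == 0) return(coords)
  with_seed(seed, {
    n <- nrow(coords)
    if (model == "isotropic") {
      coords + matrix(rnorm(3L * n, sd = noise_factor), ncol = 3L)
    } else {
      centre <- colMeans(coords)
      d <- sweep(coords, 2L, centre)
      u <- d / pmax(sqrt(rowSums(d^2)), .Machine$double.eps)
      coords + u * rnorm(n, sd = noise_factor)
    }
  })
}

#' Generate a labelled synthetic test shape
#'
#' Concatenates a uniform sphere sample (`n_outside` points, ground truth
#' outside = 1) and a uniform concentric-ball sample (`n_inside` points,
#' ground truth inside = 0), then perturbs the surface points by Gaussian
#' noise if `noise_factor > 0`. Ground-truth labels are fixed at
#' construction and are never recomputed from noisy positions.
#'
#' @param spec A [shape_spec()].
#' @return An object of class `labelled_shape`: a list with `points` (the
#'   \eqn{(n_{out}+n_{in}) \times 3} matrix, surface points first), `truth`
#'   (integer bits, 1 = outside, 0 = inside) and `spec`.
#' @export
make_test_shape <- function(spec = shape_spec()) {
  stopifnot(inherits(spec, "shape_spec"))
  with_seed(spec$seed, {
    outside <- sample_sphere_uniform(spec$n_outside, r = spec$outer_radius)
    inside <- sample_ball_uniform(spec$n_inside, r = spec$inner_radius)
    if (spec$noise_factor > 0 && spec$n_outside > 0L) {
      # noise_factor is the s.d. of the total displacement; the isotropic
      # model spreads it equally over the three coordinates
      sd_coord <- if (spec$noise_model == "isotropic")
        spec$noise_factor / sqrt(3) else spec$noise_factor
      outside <- add_surface_noise(outside, sd_coord, model = spec$noise_model)
    }
    structure(
      list(points = rbind(outside, inside),
           truth = c(rep(1L, spec$n_outside), rep(0L, spec$n_inside)),
           spec = spec),
      class = "labelled_shape"
    )
  })
}

#' @export
print.labelled_shape <- function(x, ...) {
  cat(sprintf("Labelled shape: %d outside + %d inside points (inner radius %.3g, noise %.3g)\n",
              sum(x$truth == 1L), sum(x$truth == 0L),
              x$spec$inner_radius %||% NA, x$spec$noise_factor %||% 0))
  invisible(x)
}
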