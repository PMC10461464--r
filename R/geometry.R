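#' Build the triangulated convex hull of a 3D point cloud
#'
#' Computes the convex hull of an \eqn{n \times 3} point cloud and returns it
#' as a watertight mesh of oriented triangular faces. The face set is the
#' boundary triangulation a Delaunay-based hull would produce: for a
#' triangulated convex polytope with \eqn{V} hull vertices the face count is
#' always \eqn{2V - 4}.
#'
#' @param points An \eqn{n \times 3} numeric matrix (or data frame) of
#'   Cartesian coordinates, \eqn{n \ge 4}, not all coplanar.
#' @return An object of class `triangulated_hull`: a list with
#'   \describe{
#'     \item{`vertices`}{integer indices (into `points`) of the hull vertices,}
#'     \item{`faces`}{an \eqn{F \times 3} integer matrix of vertex-index
#'       triples, one row per triangular face,}
#'     \item{`points`}{the validated coordinate matrix the hull was built
#'       from.}
#'   }
#' @examples
#' cube <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
#' h <- build_hull(cube)
#' length(h$vertices)  # 8
#' nrow(h$faces)       # 12 = 2 * 8 - 4
#' @seealso [face_distance_profile()], [classify_convex_hull()]
#' @export
build_hull <- function(points) {
  coords <- as_coords(points, n_min = 4L)
  hull <- .convex_hull_cpp(coords)
  structure(
    list(vertices = hull$vertices, faces = hull$faces, points = coords),
    class = "triangulated_hull"
  )
}

#' @export
print.triangulated_hull <- function(x, ...) {
  cat(sprintf("Triangulated convex hull: %d of %d points are hull vertices, %d faces\n",
              length(x$vertices), nrow(x$points), nrow(x$faces)))
  invisible(x)
}

#' Euclidean distance from a point to a closed triangle
#'
#' Exact distance from a 3D point to the closest point of a triangle,
#' handling the face-interior, edge and vertex regions separately
#' (no sampling or iteration involved).
#'
#' @param p Numeric vector of length 3.
#' @param tri A \eqn{3 \times 3} numeric matrix, one triangle vertex per row.
#'   Must be non-degenerate (non-zero area).
#' @return A single non-negative number.
#' @examples
#' tri <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
#' point_triangle_distance(c(0, 0, 1), tri)  # 1
#' @export
point_triangle_distance <- function(p, tri) {
  p <- as.numeric(p)
  tri <- as.matrix(tri)
  if (length(p) != 3L || !all(is.finite(p)))
    stop("`p` must be a finite 3D point")
  if (!all(dim(tri) == c(3L, 3L)) || !all(is.finite(tri)))
    stop("`tri` must be a finite 3 x 3 matrix (one vertex per row)")
  area2 <- sqrt(sum(crossprod3(tri[2L, ] - tri[1L, ], tri[3L, ] - tri[1L, ])^2))
  scale <- max(abs(tri), 1)
  if (area2 <= 1e-14 * scale^2)
    stop("degenerate face: triangle has (near) zero area")
  .pt_tri_dist_cpp(p, tri[1L, ], tri[2L, ], tri[3L, ])
}

crossprod3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Distances from a point to every face of a convex hull
#'
#' For a query point, computes the minimum distance to each triangular face
#' of a hull, and summarises them by their minimum `m` and (population)
#' variance `v` -- the two per-point quantities the insideOutside decision
#' space is built from.
#'
#' @param p Numeric vector of length 3: the query point.
#' @param hull A `triangulated_hull` from [build_hull()].
#' @return An object of class `distance_profile`: a list with
#'   `face_distances` (one non-negative distance per face), `m` (their
#'   minimum), `v` (their population variance, i.e. dividing by the number of
#'   faces), and `on_boundary` (`TRUE` when `m` is within `1e-9` times the
#'   cloud diameter of zero).
#' @examples
#' tetra <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
#' h <- build_hull(tetra)
#' face_distance_profile(colMeans(tetra), h)$v  # 0: all faces equidistant
#' @export
face_distance_profile <- function(p, hull) {
  if (!inherits(hull, "triangulated_hull"))
    stop("`hull` must be a triangulated_hull from build_hull()")
  p <- as.numeric(p)
  if (length(p) != 3L || !all(is.finite(p)))
    stop("`p` must be a finite 3D point")
  d <- .face_distances_cpp(p, hull$points, hull$faces)
  m <- min(d)
  v <- max(mean(d^2) - mean(d)^2, 0)
  structure(
    list(face_distances = d, m = m, v = v,
         on_boundary = m <= 1e-9 * cloud_diameter(hull$points)),
    class = "distance_profile"
  )
}

# Vectorised (m, v) profiles of all points of a cloud against its own hull.
# Internal workhorse of compute_features() and the sweep experiments.
profile_cloud <- function(coords, hull = NULL) {
  if (is.null(hull)) hull <- build_hull(coords)
  .distance_profile_cpp(coords, hull$points, hull$faces)
}

#' Minimum distance from an interior point to a sphere
#'
#' For a point at distance `x` from the centre of a sphere of radius `r`,
#' the nearest point of the sphere lies on the ray through the point, so the
#' minimum distance is `r - x`.
#'
#' @param x Distance(s) of the point from the sphere centre, `0 <= x <= r`.
#' @param r Sphere radius, `r > 0`.
#' @return `r - x`, vectorised over `x`.
#' @export
sphere_min_distance <- function(x, r) {
  check_sphere_args(x, r)
  r - x
}

#' Variance of distances from an interior point to a sphere
#'
#' Closed form of the surface integral for the variance of the distance from
#' a point at radius `x` to a uniformly weighted sphere of radius `r`. With
#' the point on the z-axis and a sphere point at polar angle \eqn{\phi}, the
#' law of cosines gives \eqn{d = \sqrt{r^2 + x^2 - 2rx\cos\phi}}; integrating
#' over the sphere yields \eqn{E[d] = r + x^2/(3r)} and
#' \eqn{E[d^2] = r^2 + x^2}, hence
#' \deqn{v(x) = \frac{x^2}{3} - \frac{x^4}{9 r^2}.}
#' The variance is 0 at the centre (`x = 0`, all distances equal `r`) and
#' maximal, \eqn{2r^2/9}, on the surface (`x = r`).
#'
#' @inheritParams sphere_min_distance
#' @return The variance(s), vectorised over `x`.
#' @examples
#' sphere_variance(1, 1)    # 2/9
#' sphere_variance(0.5, 1)  # 0.0763889
#' @export
sphere_variance <- function(x, r) {
  check_sphere_args(x, r)
  x^2 / 3 - x^4 / (9 * r^2)
}

#' Sphere variance as a function of the minimum distance
#'
#' Substitutes `x = r - m` into the closed-form sphere variance, giving the
#' analytic inverse relationship between the minimum distance `m` and the
#' variance in distances `v`: `v` is strictly non-increasing in `m` on
#' `[0, r]`, the relationship the insideOutside decision space exploits.
#'
#' @param m_values Minimum distances, all in `[0, r]`.
#' @param r Sphere radius.
#' @return The variance evaluated at each `m`.
#' @export
sphere_variance_vs_min_distance <- function(m_values, r) {
  check_sphere_args(m_values, r)
  sphere_variance(r - m_values, r)
}

check_sphere_args <- function(x, r) {
  if (!is.numeric(r) || length(r) != 1L || !is.finite(r) || r <= 0)
    stop("`r` must be a single positive radius")
  if (!is.numeric(x) || !all(is.finite(x)) || any(x < 0 | x > r))
    stop("point not on/inside sphere: need 0 <= x <= r")
  invisible(TRUE)
}
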