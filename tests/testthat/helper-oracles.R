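# Independent oracles and fixtures shared across the test files.

# Regular tetrahedron (circumradius sqrt(3)) and the unit cube corners.
regular_tetra <- function() {
  rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
}

cube_corners <- function() {
  as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
}

# Point-to-segment distance, closed form.
seg_dist <- function(p, a, b) {
  ab <- b - a
  t <- sum((p - a) * ab) / sum(ab^2)
  t <- min(max(t, 0), 1)
  sqrt(sum((p - (a + t * ab))^2))
}

# Independent point-to-triangle distance: orthogonal projection onto the
# triangle's plane checked by barycentric coordinates, else the minimum of
# the three edge distances. A different formulation from the region-based
# method inside the package.
oracle_tri_dist <- function(p, A, B, C) {
  n <- pracma_cross(B - A, C - A)
  n <- n / sqrt(sum(n^2))
  q <- p - sum((p - A) * n) * n        # projection onto the plane
  # barycentric test via areas
  M <- cbind(B - A, C - A)
  st <- qr.solve(M, q - A)
  if (st[1] >= 0 && st[2] >= 0 && sum(st) <= 1) {
    return(abs(sum((p - A) * n)))
  }
  min(seg_dist(p, A, B), seg_dist(p, B, C), seg_dist(p, A, C))
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Brute-force minimum distance from p to a hull: barycentric sampling of
# every face (upper bound on the true minimum, tight for large k).
oracle_hull_min_dist <- function(p, hull, k = 60) {
  g <- expand.grid(s = seq(0, 1, length.out = k), t = seq(0, 1, length.out = k))
  g <- g[g$s + g$t <= 1, ]
  best <- Inf
  for (f in seq_len(nrow(hull$faces))) {
    A <- hull$points[hull$faces[f, 1], ]
    B <- hull$points[hull$faces[f, 2], ]
    C <- hull$points[hull$faces[f, 3], ]
    pts <- outer(1 - g$s - g$t, A) + outer(g$s, B) + outer(g$t, C)
    best <- min(best, min(sqrt(rowSums(sweep(pts, 2, p)^2))))
  }
  best
}

# Numerical surface-integral oracle for the sphere distance moments:
# d(phi) = sqrt(r^2 + x^2 - 2 r x cos(phi)) against the uniform measure
# sin(phi)/2 dphi on [0, pi].
oracle_sphere_variance <- function(x, r) {
  ed <- integrate(function(phi) sqrt(r^2 + x^2 - 2 * r * x * cos(phi)) * sin(phi) / 2,
                  0, pi, rel.tol = 1e-12)$value
  ed2 <- integrate(function(phi) (r^2 + x^2 - 2 * r * x * cos(phi)) * sin(phi) / 2,
                   0, pi, rel.tol = 1e-12)$value
  ed2 - ed^2
}

# Random proper rotation matrix.
random_rotation <- function(seed) {
  withr::with_seed(seed, {
    qr_ <- qr(matrix(rnorm(9), 3))
    R <- qr.Q(qr_)
    if (det(R) < 0) R[, 1] <- -R[, 1]
    R
  })
}

# Points on an ellipsoid surface with the given radii/orientation/centre.
ellipsoid_surface_points <- function(n, radii, centre = c(0, 0, 0),
                                     rotation = diag(3), seed = 1) {
  u <- sample_sphere_uniform(n, r = 1, seed = seed)
  sweep(t(rotation %*% t(sweep(u, 2, radii, `*`))), 2, centre, `+`)
}
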