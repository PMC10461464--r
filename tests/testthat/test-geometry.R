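test_that("hulls of canonical solids have the expected vertex and face counts", {
  tetra <- build_hull(regular_tetra())
  expect_setequal(tetra$vertices, 1:4)
  expect_equal(nrow(tetra$faces), 4L)

  cube <- build_hull(cube_corners())
  expect_setequal(cube$vertices, 1:8)
  expect_equal(nrow(cube$faces), 12L)  # 2V - 4 with the face diagonals

  sph <- build_hull(sample_sphere_uniform(100, seed = 3))
  expect_setequal(sph$vertices, 1:100)  # points on a sphere are in convex position
  expect_equal(nrow(sph$faces), 196L)
})

test_that("hulls are watertight: 2V - 4 faces and every point on or inside", {
  for (seed in 1:5) {
    shape <- make_test_shape(shape_spec(inner_radius = 0.7, seed = seed))
    h <- build_hull(shape$points)
    expect_equal(nrow(h$faces), 2L * length(h$vertices) - 4L)
    # signed plane test: no point strictly outside any outward face plane
    diam <- sqrt(sum((apply(shape$points, 2, max) - apply(shape$points, 2, min))^2))
    for (f in seq_len(nrow(h$faces))) {
      A <- h$points[h$faces[f, 1], ]
      n <- pracma_cross(h$points[h$faces[f, 2], ] - A, h$points[h$faces[f, 3], ] - A)
      n <- n / sqrt(sum(n^2))
      s <- drop(shape$points %*% n) - sum(n * A)
      if (mean(s > 0) > 0.5) s <- -s  # orient outward-agnostically
      expect_lt(max(s), 1e-7 * diam)
    }
  }
})

test_that("hull construction rejects degenerate input", {
  expect_error(build_hull(regular_tetra()[1:3, ]), "insufficient points")
  flat <- cbind(matrix(runif(20), ncol = 2), 0)
  expect_error(build_hull(flat), "degenerate geometry")
  line <- cbind(1:5, 1:5, 1:5)
  expect_error(build_hull(line), "degenerate geometry")
  expect_error(build_hull(matrix(1, 6, 3)), "degenerate geometry")
})

test_that("point-triangle distance matches its closed-form cases and an independent oracle", {
  tri <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  expect_equal(point_triangle_distance(c(0, 0, 1), tri), 1.0)
  expect_equal(point_triangle_distance(c(1, 0, 0), tri), 0.0)
  expect_equal(point_triangle_distance(c(2, 2, 0), tri), sqrt(2 * 1.5^2),
               tolerance = 1e-12)  # closest point (0.5, 0.5, 0)

  withr::with_seed(42, {
    for (i in 1:50) {
      tri <- matrix(rnorm(9), 3)
      p <- rnorm(3) * 2
      expect_equal(point_triangle_distance(p, tri),
                   oracle_tri_dist(p, tri[1, ], tri[2, ], tri[3, ]),
                   tolerance = 1e-9)
    }
  })

  degenerate <- rbind(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2))
  expect_error(point_triangle_distance(c(0, 1, 0), degenerate), "degenerate face")
})

test_that("face-distance profiles respect symmetry and boundary cases", {
  tetra <- regular_tetra()
  h <- build_hull(tetra)
  prof <- face_distance_profile(colMeans(tetra), h)
  expect_equal(length(prof$face_distances), 4L)
  expect_equal(diff(range(prof$face_distances)), 0, tolerance = 1e-12)
  expect_equal(prof$v, 0, tolerance = 1e-12)

  vert <- face_distance_profile(tetra[2, ], h)
  expect_equal(vert$m, 0, tolerance = 1e-12)
  expect_true(vert$on_boundary)

  hc <- build_hull(cube_corners())
  centre <- face_distance_profile(c(0.5, 0.5, 0.5), hc)
  expect_equal(unname(centre$face_distances), rep(0.5, 12), tolerance = 1e-12)
  expect_equal(centre$m, 0.5, tolerance = 1e-12)
  expect_equal(centre$v, 0, tolerance = 1e-12)
  # brute-force surface sampling agrees
  expect_equal(oracle_hull_min_dist(c(0.5, 0.5, 0.5), hc, k = 200), 0.5,
               tolerance = 1e-4)
})

test_that("profile minimum agrees with a brute-force face-sampling oracle", {
  withr::with_seed(7, {
    for (i in 1:5) {
      shape <- make_test_shape(shape_spec(n_outside = 30, n_inside = 10,
                                          inner_radius = 0.6, seed = i))
      h <- build_hull(shape$points)
      q <- runif(3, -0.3, 0.3)
      m <- face_distance_profile(q, h)$m
      m_bf <- oracle_hull_min_dist(q, h, k = 80)
      # the sampled minimum upper-bounds the true minimum and is O(h^2) tight
      expect_gte(m_bf + 1e-12, m)
      expect_equal(m, m_bf, tolerance = 1e-3)
    }
  })
})

test_that("profiles are rigid-motion invariant and scale covariant", {
  shape <- make_test_shape(shape_spec(n_outside = 40, n_inside = 15,
                                      inner_radius = 0.5, seed = 9))
  pts <- shape$points
  prof <- insideOutside:::profile_cloud(pts)

  R <- random_rotation(11)
  tr <- c(2, -1, 0.5)
  moved <- sweep(pts %*% t(R), 2, tr, `+`)
  prof_m <- insideOutside:::profile_cloud(moved)
  expect_equal(prof_m$m, prof$m, tolerance = 1e-9)
  expect_equal(prof_m$v, prof$v, tolerance = 1e-9)
  # multiset of face distances for a single query is preserved too
  h <- build_hull(pts); hm <- build_hull(moved)
  d1 <- sort(face_distance_profile(pts[50, ], h)$face_distances)
  d2 <- sort(face_distance_profile(moved[50, ], hm)$face_distances)
  expect_equal(d1, d2, tolerance = 1e-9)

  s <- 3.7
  prof_s <- insideOutside:::profile_cloud(pts * s)
  expect_equal(prof_s$m, s * prof$m, tolerance = 1e-9)
  expect_equal(prof_s$v, s^2 * prof$v, tolerance = 1e-9)
})

test_that("closed-form sphere variance matches the surface-integral oracle", {
  expect_equal(sphere_min_distance(0, 1), 1)
  expect_equal(sphere_min_distance(1, 1), 0)
  expect_equal(sphere_min_distance(0.3, 2), 1.7)
  expect_error(sphere_min_distance(1.5, 1), "point not on/inside sphere")

  expect_equal(sphere_variance(0, 1), 0)
  for (x in c(0.1, 0.25, 0.5, 0.8, 1)) {
    expect_equal(sphere_variance(x, 1), oracle_sphere_variance(x, 1),
                 tolerance = 1e-6)
  }
  expect_equal(sphere_variance(1.3, 2.6), oracle_sphere_variance(1.3, 2.6),
               tolerance = 1e-6)
  expect_equal(sphere_variance(1, 1), 2 / 9, tolerance = 1e-12)
})

test_that("variance is a non-increasing function of the minimum distance", {
  m <- seq(0, 1, length.out = 200)
  v <- sphere_variance_vs_min_distance(m, r = 1)
  expect_equal(v[1], 2 / 9, tolerance = 1e-12)
  expect_equal(v[200], 0)
  expect_true(all(diff(v) <= 1e-12))
  expect_error(sphere_variance_vs_min_distance(c(0.5, 1.2), 1),
               "point not on/inside sphere")
})

test_that("discrete sphere (m, v) curves converge to the analytic curve", {
  probe <- test_points_along_radius(50, r = 1, direction = c(0, 0, 1))
  x <- sqrt(rowSums(probe^2))
  dev_for_n <- function(n) {
    h <- build_hull(equidistant_sphere_points(n))
    prof <- insideOutside:::profile_cloud(probe, h)
    max(abs(prof$v - sphere_variance(x, 1)))
  }
  d100 <- dev_for_n(100)
  d400 <- dev_for_n(400)
  expect_lt(d100, 0.05)   # already close at the 100-point discretisation
  expect_lt(d400, d100)   # and converging as the surface is refined

  # uniform random surfaces behave like the equidistant one
  h <- build_hull(sample_sphere_uniform(100, seed = 2))
  prof <- insideOutside:::profile_cloud(probe, h)
  expect_lt(max(abs(prof$v - sphere_variance(x, 1))), 0.08)
})
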