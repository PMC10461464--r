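test_that("decision-space features separate a centroid from simplex vertices", {
  pts <- rbind(regular_tetra(), c(0, 0, 0))
  f <- compute_features(pts, io_config())
  expect_equal(unname(f$features[5, "f1"]), 1)        # unique maximal distance
  expect_equal(unname(f$features[1:4, "f1"]), rep(0, 4))
  # before the final rescale, hull vertices sit at log10(epsilon) = -2
  expect_equal(unname(f$f1_pre[1:4]), rep(-2, 4))
  expect_true(all(f$features >= 0 & f$features <= 1))
})

test_that("ball points occupy the high-f1/low-f2 corner, sphere points the opposite", {
  shape <- make_test_shape(shape_spec(inner_radius = 0.5, seed = 8))
  f <- compute_features(shape$points, io_config())
  inside <- shape$truth == 0L
  expect_gt(mean(f$features[inside, "f1"]), mean(f$features[!inside, "f1"]) + 0.3)
  expect_lt(mean(f$features[inside, "f2"]), mean(f$features[!inside, "f2"]) - 0.3)
})

test_that("feature computation reports degenerate scalings by name", {
  expect_error(compute_features(regular_tetra()), "insufficient points")
  # every point a hull vertex -> m identically zero -> scaling undefined
  expect_error(compute_features(sample_sphere_uniform(20, seed = 1)),
               "constant feature: minimum distance")
})

test_that("the clustering back-ends recover well-separated feature blobs", {
  X <- withr::with_seed(10, rbind(
    cbind(rnorm(50, 1, 0.02), rnorm(50, 0, 0.02)),
    cbind(rnorm(100, 0, 0.02), rnorm(100, 1, 0.02))
  ))
  truth_blob <- rep(1:2, c(50, 100))
  for (method in c("hierarchical", "kmeans", "dbscan", "spectral")) {
    g <- cluster_features(X, method = method, config = io_config(seed = 1))
    expect_length(g, 150L)
    expect_setequal(unique(g), 1:2)
    # partition identical to the blob structure (up to label swap)
    agree <- max(mean((g == 1) == (truth_blob == 1)),
                 mean((g == 2) == (truth_blob == 1)))
    expect_equal(agree, 1, info = method)
  }
})

test_that("degenerate clustering inputs fail loudly or split deterministically", {
  one_blob <- matrix(rep(c(0.5, 0.5), each = 20), ncol = 2)
  expect_error(cluster_features(one_blob, method = "hierarchical"), "cannot split")
  # duplicated rows but two distinct values: deterministic split, no crash
  dup <- rbind(matrix(rep(c(0, 0), 10), ncol = 2, byrow = TRUE),
               matrix(rep(c(1, 1), 10), ncol = 2, byrow = TRUE))
  g1 <- cluster_features(dup, method = "hierarchical")
  g2 <- cluster_features(dup, method = "hierarchical")
  expect_identical(g1, g2)
  expect_setequal(unique(g1), 1:2)
  # DBSCAN with a hopeless eps reports its failure
  expect_error(cluster_features(dup, method = "dbscan",
                                config = io_config(dbscan_eps = 5)),
               "clustering failed, adjust parameters")
})

test_that("inside/outside assignment depends on features, not group numbering", {
  pts <- rbind(regular_tetra(), c(0, 0, 0))
  f <- compute_features(pts, io_config())
  g <- c(1L, 1L, 1L, 1L, 2L)
  res <- assign_inside_outside(g, f)
  expect_identical(res$labels, c(1L, 1L, 1L, 1L, 0L))
  res_swapped <- assign_inside_outside(3L - g, f)
  expect_identical(res_swapped$labels, res$labels)
})

test_that("the classifier is near-perfect on well-separated simulated shapes", {
  for (seed in 1:3) {
    shape <- make_test_shape(shape_spec(inner_radius = 0.1, seed = seed))
    res <- inside_outside(shape)
    expect_identical(res$labels, shape$truth)
  }
})

test_that("labels are invariant under rigid motion and uniform scaling", {
  shape <- make_test_shape(shape_spec(inner_radius = 0.6, seed = 12))
  base <- inside_outside(shape)$labels
  R <- random_rotation(5)
  moved <- sweep(shape$points %*% t(R), 2, c(10, -3, 2), `+`)
  expect_identical(inside_outside(moved)$labels, base)
  expect_identical(inside_outside(shape$points * 250)$labels, base)
  expect_identical(inside_outside(shape$points * 1e-3)$labels, base)
})

test_that("the log transform rescues the raw feature's failure at inner radius 1", {
  seeds <- withr::with_seed(31, sample.int(2^31 - 1, 40))
  ti <- function(cfg) {
    mean(vapply(seeds, function(s) {
      sh <- make_test_shape(shape_spec(inner_radius = 1, seed = s))
      classification_rates(sh$truth, inside_outside(sh, cfg)$labels)[1]
    }, numeric(1)))
  }
  ti_raw <- ti(io_config(transform = "raw", feature_mode = "m-only"))
  ti_log <- ti(io_config())
  expect_lt(ti_raw, 0.65)          # raw minimum distance collapses
  expect_gt(ti_log, 0.75)          # log decision space stays usable
  expect_gt(ti_log, ti_raw + 0.2)
})

test_that("the variance feature alone is a poor classifier relative to the bivariate space", {
  seeds <- withr::with_seed(77, sample.int(2^31 - 1, 20))
  rates <- function(cfg) {
    colMeans(t(vapply(seeds, function(s) {
      sh <- make_test_shape(shape_spec(inner_radius = 1, seed = s))
      classification_rates(sh$truth, inside_outside(sh, cfg)$labels)
    }, numeric(2))))
  }
  r_biv <- rates(io_config())
  r_v <- rates(io_config(feature_mode = "v-only"))
  expect_gt(r_biv[1], r_v[1] + 0.1)
  expect_gt(mean(r_biv), mean(r_v) + 0.05)
})
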