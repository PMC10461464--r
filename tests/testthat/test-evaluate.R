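test_that("designations follow the four-way truth/prediction table", {
  d <- designate(truth = c(0, 0, 1, 1), predicted = c(0, 1, 1, 0))
  expect_equal(as.character(d),
               c("true inside", "misclassified inside",
                 "true outside", "misclassified outside"))
  expect_error(designate(c(0, 1), c(0, 1, 1)), "equal length")
  expect_error(designate(c(0, 2), c(0, 1)), "bits")
})

test_that("rates are class-conditional fractions with the algebraic identity", {
  truth <- rep(c(0, 1), c(10, 20))
  pred <- truth
  pred[1:2] <- 1  # two inside points misclassified
  pred[11:13] <- 0  # three outside points misclassified
  d <- designate(truth, pred)
  expect_equal(true_inside_rate(d), 0.8)
  expect_equal(true_outside_rate(d), 17 / 20)
  # Eq-3 identity: rate == 1 - misclassified / class size, exactly
  expect_identical(true_inside_rate(d), 1 - sum(d == "misclassified inside") / 10)
  expect_identical(true_outside_rate(d), 1 - sum(d == "misclassified outside") / 20)
  # the four designations partition the points
  expect_identical(sum(table(d)), length(truth))

  expect_equal(unname(classification_rates(truth, truth)), c(1, 1))
  expect_equal(true_inside_rate(designate(rep(0, 5), rep(1, 5))), 0)
  expect_error(true_inside_rate(designate(rep(1, 5), rep(1, 5))), "rate undefined")
})

test_that("radius sweeps are tidy, reproducible, and sensible at easy radii", {
  sw <- radius_sweep(c(0.1, 0.5), n_replicates = 5, seed = 3)
  expect_s3_class(sw, "io_sweep")
  expect_equal(nrow(sw), 2L)
  expect_named(as.data.frame(sw),
               c("radius", "mean_ti", "sd_ti", "mean_to", "sd_to", "n", "n_failed"))
  expect_true(all(sw$mean_ti >= 0 & sw$mean_ti <= 1))
  expect_equal(sw$mean_ti[1], 1)  # trivially separable at radius 0.1
  expect_equal(sw$n, c(5L, 5L))
  sw2 <- radius_sweep(c(0.1, 0.5), n_replicates = 5, seed = 3)
  expect_identical(as.data.frame(sw), as.data.frame(sw2))
})

test_that("epsilon sweeps report per-epsilon worst cases over radii", {
  sw <- epsilon_sweep(radii = c(0.3, 0.95), epsilons = c(0.01, 0.1),
                      n_replicates = 4, seed = 5)
  expect_equal(nrow(sw), 4L)
  worst <- attr(sw, "worst_case")
  expect_equal(worst$epsilon, c(0.01, 0.1))
  for (k in 1:2) {
    sub <- sw[sw$epsilon == worst$epsilon[k], ]
    expect_equal(worst$worst_ti[k], min(sub$mean_ti))
    expect_true(worst$at_radius[k] %in% sub$radius)
  }
})

test_that("noise sweeps pair methods on identical shapes", {
  sw <- noise_sweep(radii = c(0.3, 0.6), noise_factors = c(0, 0.1),
                    n_replicates = 4, seed = 6)
  d <- as.data.frame(sw)
  expect_equal(nrow(d), 8L)  # 2 radii x 2 noise x 2 methods
  # noiseless sphere points are all hull vertices: Convex Hull TO is exactly 1
  ch0 <- d[d$method == "convexhull" & d$noise_factor == 0, ]
  expect_equal(ch0$mean_to, c(1, 1))
  expect_identical(as.data.frame(noise_sweep(radii = c(0.3, 0.6),
                                             noise_factors = c(0, 0.1),
                                             n_replicates = 4, seed = 6)), d)
})

test_that("leave-K-out subsampling matches the published protocol", {
  shape <- list(points = sample_ball_uniform(35, seed = 1),
                truth = rep(c(0L, 1L), c(15, 20)))
  loo <- leave_k_out_subsample(shape, k = 1)
  expect_length(loo, 35L)
  expect_true(all(vapply(loo, function(s) nrow(s$points), numeric(1)) == 34))
  # each subset's truth is the restriction of the parent's
  expect_identical(loo[[1]]$truth, shape$truth[-1])

  k5 <- leave_k_out_subsample(shape, k = 5, n_samples = 100, seed = 2)
  expect_length(k5, 100L)
  expect_true(all(vapply(k5, function(s) nrow(s$points), numeric(1)) == 30))
  expect_identical(leave_k_out_subsample(shape, k = 5, seed = 2)[[10]]$truth,
                   k5[[10]]$truth)
  expect_error(leave_k_out_subsample(shape, k = 35), "must satisfy")
})

test_that("GMM thresholding recovers a well-separated two-component signal", {
  sim <- withr::with_seed(11, {
    comp <- rep(0:1, each = 500)
    list(comp = comp, values = rnorm(1000, mean = ifelse(comp == 1, 0.8, 0.2),
                                     sd = 0.05))
  })
  fit <- gmm_threshold(sim$values, log_transform = FALSE)
  expect_gt(mean(fit$labels == sim$comp), 0.99)
  expect_equal(fit$means[1] < fit$means[2], TRUE)
  # positive scaling of the raw values is absorbed by the rescaling
  fit3 <- gmm_threshold(sim$values * 3, log_transform = FALSE)
  expect_identical(fit3$labels, fit$labels)
  # volume normalisation route
  vols <- withr::with_seed(12, runif(1000, 0.5, 2))
  fitv <- gmm_threshold((10^sim$values) * vols, volumes = vols, log_transform = TRUE)
  expect_gt(mean(fitv$labels == sim$comp), 0.99)
  expect_error(gmm_threshold(rep(2, 10)), "degenerate")
})

test_that("benchmarks run all four classifiers on one labelled cloud", {
  shape <- make_test_shape(shape_spec(inner_radius = 0.3, seed = 13))
  tab <- benchmark_methods(shape, config = io_config(seed = 1))
  expect_equal(nrow(tab), 4L)
  expect_true(all(tab$true_inside >= 0 & tab$true_inside <= 1))
  # hull-based methods are near-perfect on an easy noiseless shape
  hullish <- tab$method %in% c("insideoutside", "convexhull")
  expect_true(all(tab$true_inside[hullish] == 1))
  expect_true(all(tab$true_outside[hullish] == 1))
})
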