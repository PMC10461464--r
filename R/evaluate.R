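#' Four-way accuracy designations
#'
#' Compares construction ground truth with predicted labels and assigns each
#' point one of four designations: a point is "true inside" when truth and
#' prediction are both inside, "misclassified inside" when an inside point
#' is predicted outside, and symmetrically for the outside designations.
#'
#' @param truth Integer bits, 0 = inside, 1 = outside (ground truth).
#' @param predicted Integer bits of equal length (predicted labels).
#' @return A factor with levels `"true inside"`, `"misclassified inside"`,
#'   `"true outside"`, `"misclassified outside"`.
#' @export
designate <- function(truth, predicted) {
  truth <- as.integer(truth)
  predicted <- as.integer(predicted)
  if (length(truth) != length(predicted))
    stop("`truth` and `predicted` must have equal length")
  if (!all(truth %in% 0:1) || !all(predicted %in% 0:1))
    stop("labels must be bits: 0 (inside) or 1 (outside)")
  out <- ifelse(truth == 0L,
                ifelse(predicted == 0L, "true inside", "misclassified inside"),
                ifelse(predicted == 1L, "true outside", "misclassified outside"))
  factor(out, levels = c("true inside", "misclassified inside",
                         "true outside", "misclassified outside"))
}

#' Class-conditional correct-classification rates
#'
#' The true inside rate is the number of "true inside" points divided by the
#' number of ground-truth inside points (the sensitivity of the inside
#' class); the true outside rate is defined symmetrically.
#'
#' @param designations A factor from [designate()].
#' @return A single rate in \[0, 1\].
#' @export
true_inside_rate <- function(designations) {
  n_in <- sum(designations %in% c("true inside", "misclassified inside"))
  if (n_in == 0L) stop("rate undefined: no ground-truth inside points")
  sum(designations == "true inside") / n_in
}

#' @rdname true_inside_rate
#' @export
true_outside_rate <- function(designations) {
  n_out <- sum(designations %in% c("true outside", "misclassified outside"))
  if (n_out == 0L) stop("rate undefined: no ground-truth outside points")
  sum(designations == "true outside") / n_out
}

#' @rdname true_inside_rate
#' @param truth,predicted Bit vectors, as in [designate()].
#' @return For `classification_rates()`, a named vector
#'   `c(true_inside, true_outside)`.
#' @export
classification_rates <- function(truth, predicted) {
  d <- designate(truth, predicted)
  c(true_inside = true_inside_rate(d), true_outside = true_outside_rate(d))
}

# Run `n_replicates` seeded shape+classify replicates for one parameter
# setting and return the TI/TO rates of the successful ones. `classifier`
# maps a labelled_shape to an integer label vector. Replicates whose
# classifier errors are dropped (their count is reported).
run_replicates <- function(spec_template, n_replicates, classifier, seeds) {
  ti <- to <- rep(NA_real_, n_replicates)
  for (i in seq_len(n_replicates)) {
    spec <- spec_template
    spec$seed <- seeds[i]
    shape <- make_test_shape(spec)
    rates <- tryCatch(classification_rates(shape$truth, classifier(shape)),
                      error = function(e) c(NA_real_, NA_real_))
    ti[i] <- rates[1L]
    to[i] <- rates[2L]
  }
  list(ti = ti, to = to, n_failed = sum(is.na(ti)))
}

summarise_rates <- function(rep) {
  data.frame(
    mean_ti = mean(rep$ti, na.rm = TRUE), sd_ti = sd(rep$ti, na.rm = TRUE),
    mean_to = mean(rep$to, na.rm = TRUE), sd_to = sd(rep$to, na.rm = TRUE),
    n = sum(!is.na(rep$ti)), n_failed = rep$n_failed
  )
}

#' Inner-ball-radius sweep of classification accuracy
#'
#' For each inner ball radius, simulates `n_replicates` blastocyst-like
#' shapes (by default 100 sphere points + 50 ball points), classifies each
#' with the insideOutside classifier, and summarises the True Inside and
#' True Outside rates by their mean and standard deviation across
#' replicates. Replicates where the classifier errors are dropped from the
#' means and counted in `n_failed`.
#'
#' @param radii Inner ball radii, all in (0, 1\] (times `outer_radius`).
#' @param n_replicates Shapes per radius (default 100).
#' @param config An [io_config()] for the classifier.
#' @param n_outside,n_inside,outer_radius Shape parameters passed to
#'   [shape_spec()].
#' @param seed Master seed: every replicate draws its own sub-seed from it,
#'   so the whole sweep is bit-reproducible.
#' @return A data frame of class `io_sweep` with one row per radius and
#'   columns `radius`, `mean_ti`, `sd_ti`, `mean_to`, `sd_to`, `n`,
#'   `n_failed`.
#' @export
radius_sweep <- function(radii, n_replicates = 100L, config = io_config(),
                         n_outside = 100L, n_inside = 50L, outer_radius = 1,
                         seed = NULL) {
  stopifnot(all(radii > 0), all(radii <= outer_radius))
  seeds <- matrix(draw_seeds(length(radii) * n_replicates, seed),
                  nrow = n_replicates)
  rows <- lapply(seq_along(radii), function(j) {
    spec <- shape_spec(n_outside = n_outside, n_inside = n_inside,
                       inner_radius = radii[j], outer_radius = outer_radius)
    rep <- run_replicates(spec, n_replicates,
                          function(s) inside_outside(s$points, config)$labels,
                          seeds[, j])
    cbind(data.frame(radius = radii[j]), summarise_rates(rep))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("io_sweep", "data.frame")
  attr(out, "sweep_type") <- "radius"
  out
}

#' Epsilon robustness sweep
#'
#' Grid of mean True Inside rates over inner ball radius and the log-offset
#' \eqn{\epsilon}, plus the per-\eqn{\epsilon} worst case over radii (the
#' minimum mean True Inside rate, and the radius where it is attained).
#'
#' @param radii Inner ball radii in (0, 1\].
#' @param epsilons Values of \eqn{\epsilon}, all in (0, 1).
#' @param n_replicates Shapes per (radius, epsilon) cell.
#' @param config Base [io_config()]; its `epsilon` is overridden cell-wise.
#' @inheritParams radius_sweep
#' @return An `io_sweep` data frame with columns `epsilon`, `radius`,
#'   `mean_ti`, `sd_ti`, `mean_to`, `sd_to`, `n`, `n_failed`, and an
#'   attribute `"worst_case"`: a data frame with one row per `epsilon`
#'   giving `worst_ti` and `at_radius`.
#' @export
epsilon_sweep <- function(radii, epsilons, n_replicates = 100L,
                          config = io_config(), n_outside = 100L,
                          n_inside = 50L, seed = NULL) {
  stopifnot(all(epsilons > 0), all(epsilons < 1))
  sub_seeds <- draw_seeds(length(epsilons), seed)
  rows <- lapply(seq_along(epsilons), function(k) {
    cfg <- config
    cfg$epsilon <- epsilons[k]
    sw <- radius_sweep(radii, n_replicates, cfg, n_outside, n_inside,
                       seed = sub_seeds[k])
    cbind(data.frame(epsilon = epsilons[k]), as.data.frame(sw))
  })
  out <- do.call(rbind, rows)
  worst <- do.call(rbind, lapply(split(out, out$epsilon), function(d) {
    j <- which.min(d$mean_ti)
    data.frame(epsilon = d$epsilon[1L], worst_ti = d$mean_ti[j],
               at_radius = d$radius[j])
  }))
  rownames(worst) <- NULL
  class(out) <- c("io_sweep", "data.frame")
  attr(out, "sweep_type") <- "epsilon"
  attr(out, "worst_case") <- worst
  out
}

#' Surface-noise sweep comparing classifiers
#'
#' Grid over inner ball radius and noise factor: for each cell,
#' `n_replicates` shapes are simulated with Gaussian noise applied to the
#' surface points, and each requested method classifies the *same* shapes
#' (a paired comparison). Means and standard deviations of the True Inside
#' and True Outside rates are reported per cell and method.
#'
#' @param radii Inner ball radii in (0, 1\].
#' @param noise_factors Noise factors (per-coordinate Gaussian s.d. on the
#'   unit-sphere scale), typically in \[0, 0.25\].
#' @param methods Any of `"insideoutside"`, `"convexhull"`,
#'   `"ellipsoid-naive"`, `"ellipsoid-ransac"`.
#' @inheritParams radius_sweep
#' @return An `io_sweep` data frame with columns `method`, `radius`,
#'   `noise_factor`, `mean_ti`, `sd_ti`, `mean_to`, `sd_to`, `n`,
#'   `n_failed`.
#' @export
noise_sweep <- function(radii, noise_factors,
                        methods = c("insideoutside", "convexhull"),
                        n_replicates = 100L, config = io_config(),
                        n_outside = 100L, n_inside = 50L, seed = NULL) {
  stopifnot(all(radii > 0), all(radii <= 1), all(noise_factors >= 0))
  methods <- match.arg(methods, c("insideoutside", "convexhull",
                                  "ellipsoid-naive", "ellipsoid-ransac"),
                       several.ok = TRUE)
  grid <- expand.grid(radius = radii, noise_factor = noise_factors,
                      KEEP.OUT.ATTRS = FALSE)
  seeds <- matrix(draw_seeds(nrow(grid) * n_replicates, seed),
                  nrow = n_replicates)
  rows <- list()
  for (g in seq_len(nrow(grid))) {
    spec <- shape_spec(n_outside = n_outside, n_inside = n_inside,
                       inner_radius = grid$radius[g],
                       noise_factor = grid$noise_factor[g])
    acc <- lapply(methods, function(m) list(ti = numeric(0), to = numeric(0), fail = 0L))
    names(acc) <- methods
    for (i in seq_len(n_replicates)) {
      spec$seed <- seeds[i, g]
      shape <- make_test_shape(spec)
      for (m in methods) {
        rates <- tryCatch(
          classification_rates(shape$truth, classify_by_method(shape$points, m, config)),
          error = function(e) NULL)
        if (is.null(rates)) {
          acc[[m]]$fail <- acc[[m]]$fail + 1L
        } else {
          acc[[m]]$ti <- c(acc[[m]]$ti, rates[1L])
          acc[[m]]$to <- c(acc[[m]]$to, rates[2L])
        }
      }
    }
    for (m in methods) {
      rows[[length(rows) + 1L]] <- data.frame(
        method = m, radius = grid$radius[g], noise_factor = grid$noise_factor[g],
        mean_ti = mean(acc[[m]]$ti), sd_ti = sd(acc[[m]]$ti),
        mean_to = mean(acc[[m]]$to), sd_to = sd(acc[[m]]$to),
        n = length(acc[[m]]$ti), n_failed = acc[[m]]$fail
      )
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("io_sweep", "data.frame")
  attr(out, "sweep_type") <- "noise"
  out
}

# Dispatch a method name to its classifier; shared by noise_sweep(),
# benchmark_methods() and the command-line interface.
classify_by_method <- function(points, method, config = io_config(),
                               rconfig = ransac_config(seed = config$seed)) {
  switch(method,
    "insideoutside"    = inside_outside(points, config)$labels,
    "convexhull"       = classify_convex_hull(points)$labels,
    "ellipsoid-naive"  = classify_ellipsoid(points, method = "naive")$labels,
    "ellipsoid-ransac" = classify_ellipsoid(points, method = "ransac",
                                            config = rconfig)$labels,
    stop(sprintf("unknown method '%s'", method))
  )
}

#' Benchmark all classifiers on a labelled cloud
#'
#' Runs each requested classifier on a labelled point cloud (empirical, e.g.
#' read from a centroid table with a ground-truth column, or simulated) and
#' tabulates the True Inside and True Outside rates.
#'
#' @param shape A `labelled_shape`, or any list with `points` and `truth`.
#' @param methods Methods to benchmark (see [noise_sweep()]).
#' @param config,rconfig Classifier configurations.
#' @return A data frame with one row per method and columns `method`,
#'   `true_inside`, `true_outside`.
#' @export
benchmark_methods <- function(shape,
                              methods = c("insideoutside", "convexhull",
                                          "ellipsoid-naive", "ellipsoid-ransac"),
                              config = io_config(),
                              rconfig = ransac_config(seed = config$seed)) {
  if (is.null(shape$points) || is.null(shape$truth))
    stop("`shape` must carry both points and ground-truth labels")
  rows <- lapply(methods, function(m) {
    rates <- classification_rates(shape$truth,
                                  classify_by_method(shape$points, m, config, rconfig))
    data.frame(method = m, true_inside = rates[1L], true_outside = rates[2L])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Leave-K-out subsampling of a labelled cloud
#'
#' Emulates segmentation/imaging error by removing `k` points per replicate.
#' For `k = 1` every point is left out once (`n` subsets of size `n - 1`);
#' for `k > 1`, `n_samples` subsets of size `n - k` are drawn (subsets with
#' replacement, points within a subset without). Each subset's truth labels
#' are the restriction of the parent's.
#'
#' @param shape A `labelled_shape` (or list with `points` and `truth`).
#' @param k Number of points to leave out, `1 <= k < n`.
#' @param n_samples Number of subsets when `k > 1` (default 100).
#' @param seed Optional integer seed.
#' @return A list of `labelled_shape` objects.
#' @export
leave_k_out_subsample <- function(shape, k, n_samples = 100L, seed = NULL) {
  coords <- as_coords(shape$points)
  truth <- as.integer(shape$truth)
  n <- nrow(coords)
  if (k < 1L || k >= n) stop("`k` must satisfy 1 <= k < n")
  subset_shape <- function(idx) {
    structure(list(points = coords[idx, , drop = FALSE], truth = truth[idx],
                   spec = list(parent_n = n, k = k)),
              class = "labelled_shape")
  }
  if (k == 1L) {
    lapply(seq_len(n), function(i) subset_shape(setdiff(seq_len(n), i)))
  } else {
    with_seed(seed, {
      lapply(seq_len(n_samples),
             function(i) subset_shape(sort(sample.int(n, n - k))))
    })
  }
}

#' Two-component Gaussian-mixture thresholding of a 1D signal
#'
#' The ground-truth utility used to dichotomise a per-nucleus marker signal
#' (e.g. a lineage-marker immunofluorescence intensity): the values are
#' normalised (divided by per-point volume when given, log10-transformed
#' when `log_transform = TRUE`, then min-max rescaled to \[0, 1\]), a
#' two-component univariate Gaussian mixture is fitted, and each point is
#' assigned to its higher-posterior component. The component with the larger
#' mean is the positive class. Because of the rescaling, multiplying all raw
#' values by a positive constant leaves the labels unchanged.
#'
#' @param values Per-point signal values.
#' @param volumes Optional per-point volumes to normalise by.
#' @param log_transform Apply a log10 transform (default `TRUE`; requires
#'   strictly positive normalised values).
#' @return A list with `labels` (integer bits, 1 = positive component),
#'   `normalized` (the \[0, 1\] values the mixture was fitted to),
#'   `means`, `sds` and `proportions` of the two fitted components
#'   (positive component second), and the fitted `mclust` model.
#' @export
gmm_threshold <- function(values, volumes = NULL, log_transform = TRUE) {
  v <- as.numeric(values)
  if (!all(is.finite(v))) stop("`values` must be finite")
  if (!is.null(volumes)) {
    volumes <- as.numeric(volumes)
    if (length(volumes) != length(v) || any(!is.finite(volumes)) || any(volumes <= 0))
      stop("`volumes` must be positive and match `values` in length")
    v <- v / volumes
  }
  if (log_transform) {
    if (any(v <= 0)) stop("log10 transform requires strictly positive values")
    v <- log10(v)
  }
  if (length(unique(v)) < 2L)
    stop("degenerate input: values are constant after normalization")
  v01 <- rescale01(v, what = "normalized signal")
  fit <- mclust::Mclust(v01, G = 2L, verbose = FALSE)
  if (is.null(fit)) stop("Gaussian mixture fit failed")
  mu <- fit$parameters$mean
  pos <- which.max(mu)
  sigmas <- sqrt(fit$parameters$variance$sigmasq)
  if (length(sigmas) == 1L) sigmas <- rep(sigmas, 2L)  # equal-variance model
  ord <- order(mu)
  list(labels = as.integer(fit$classification == pos),
       normalized = v01,
       means = unname(mu[ord]), sds = unname(sigmas[ord]),
       proportions = unname(fit$parameters$pro[ord]),
       model = fit)
}

#' @export
print.io_sweep <- function(x, ...) {
  cat(sprintf("Accuracy sweep (%s): %d cells\n",
              attr(x, "sweep_type") %||% "custom", nrow(x)))
  print.data.frame(head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat(sprintf("... %d more rows\n", nrow(x) - 10L))
  invisible(x)
}

#' Plot an accuracy sweep
#'
#' Radius sweeps are drawn as rate-versus-radius curves with a +/- 1 s.d.
#' ribbon; epsilon and noise sweeps as heatmaps of the mean rate over their
#' parameter grid. Requires ggplot2.
#'
#' @param x An `io_sweep`.
#' @param rate `"ti"` (True Inside, default) or `"to"` (True Outside).
#' @return A ggplot object.
#' @export
plot_sweep <- function(x, rate = c("ti", "to")) {
  rate <- match.arg(rate)
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_sweep() requires the ggplot2 package")
  d <- as.data.frame(x)
  d$mean_rate <- d[[paste0("mean_", rate)]]
  d$sd_rate <- d[[paste0("sd_", rate)]]
  type <- attr(x, "sweep_type") %||% "radius"
  lab <- if (rate == "ti") "True Inside rate" else "True Outside rate"
  if (type == "radius") {
    ggplot2::ggplot(d, ggplot2::aes(x = .data$radius, y = .data$mean_rate)) +
      ggplot2::geom_ribbon(ggplot2::aes(ymin = pmax(.data$mean_rate - .data$sd_rate, 0),
                                        ymax = pmin(.data$mean_rate + .data$sd_rate, 1)),
                           alpha = 0.25) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "Inner ball radius", y = lab)
  } else if (type == "epsilon") {
    ggplot2::ggplot(d, ggplot2::aes(x = .data$radius, y = factor(.data$epsilon),
                                    fill = .data$mean_rate)) +
      ggplot2::geom_tile() +
      ggplot2::labs(x = "Inner ball radius", y = "epsilon", fill = lab)
  } else {
    ggplot2::ggplot(d, ggplot2::aes(x = .data$radius, y = .data$noise_factor,
                                    fill = .data$mean_rate)) +
      ggplot2::geom_tile() +
      ggplot2::facet_wrap(~method) +
      ggplot2::labs(x = "Inner ball radius", y = "Noise factor", fill = lab)
  }
}
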