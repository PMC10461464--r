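Package: insideOutside
Title: Classification of Interior and Exterior Points of 3D Point Clouds
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unsupervised classification of the interior and exterior points of
    a three-dimensional point cloud, designed for nuclear centroids of
    pre-implantation embryos (inner cell mass versus trophectoderm) but
    applicable to any convex-ish cloud. Implements the insideOutside
    algorithm: distances from every point to every triangular face of the
    cloud's convex hull are summarised per point by their minimum and
    variance, transformed to a two-dimensional decision space, and split into
    two groups by Ward hierarchical clustering. Also provides the competitor
    classifiers used for benchmarking (naive and RANSAC ellipsoid fits with
    the 0.95 distance rule, and convex-hull boundary membership), a synthetic
    blastocyst-like shape simulator with controllable surface noise, accuracy
    designations and rates, parameter-sweep experiments, leave-K-out
    subsampling, a 1D Gaussian-mixture thresholding utility for marker
    intensities, and CSV input/output with a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    withr,
    mclust,
    kernlab
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
NeedsCompilation: yes
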