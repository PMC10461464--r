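#' Read a centroid table
#'
#' Reads an (id, x, y, z) table of nuclear-centroid coordinates, e.g. an
#' export from a segmentation tool, with optional `volume`, `intensity` and
#' `truth` columns. Column names are matched case-insensitively and can be
#' remapped via `columns`; row order is preserved.
#'
#' @param path Path to a CSV or TSV file with a header row.
#' @param format `"auto"` (by file extension; default), `"csv"` or `"tsv"`.
#' @param columns Named list overriding the default column mapping, e.g.
#'   `list(x = "Position X", truth = "label")`. Recognised roles: `id`, `x`,
#'   `y`, `z`, `volume`, `intensity`, `truth`.
#' @return A list of class `centroid_table` with `points` (\eqn{n \times 3}
#'   matrix), `ids`, and any of `volume`, `intensity`, `truth` present in
#'   the file. When a `truth` column is present the result also carries
#'   class `labelled_shape`, so it can be fed directly to
#'   [benchmark_methods()] or [classification_rates()].
#' @export
read_centroids <- function(path, format = c("auto", "csv", "tsv"),
                           columns = list()) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (format == "auto")
    format <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "tsv" else "csv"
  df <- read.csv(path, sep = if (format == "tsv") "\t" else ",",
                 check.names = FALSE, stringsAsFactors = FALSE)

  mapping <- list(id = "id", x = "x", y = "y", z = "z", volume = "volume",
                  intensity = "intensity", truth = "truth")
  mapping[names(columns)] <- columns
  find_col <- function(role) {
    hit <- which(tolower(names(df)) == tolower(mapping[[role]]))
    if (length(hit)) hit[1L] else NA_integer_
  }
  idx <- vapply(names(mapping), find_col, integer(1L))

  missing_xyz <- c("x", "y", "z")[is.na(idx[c("x", "y", "z")])]
  if (length(missing_xyz))
    stop(sprintf("missing column(s): %s",
                 paste(unlist(mapping[missing_xyz]), collapse = ", ")))

  coords <- matrix(NA_real_, nrow(df), 3L, dimnames = list(NULL, c("x", "y", "z")))
  for (j in 1:3) {
    raw <- df[[idx[c("x", "y", "z")[j]]]]
    num <- suppressWarnings(as.numeric(raw))
    bad_parse <- which(is.na(num) & !is.na(raw) & raw != "NA" & raw != "NaN")
    if (length(bad_parse))
      stop(sprintf("non-numeric coordinates in column '%s' (first at row %d)",
                   mapping[[c("x", "y", "z")[j]]], bad_parse[1L]))
    coords[, j] <- num
  }
  bad <- which(!is.finite(coords))
  if (length(bad))
    stop(sprintf("non-finite coordinate at row %d", ((bad[1L] - 1L) %% nrow(df)) + 1L))

  ids <- if (!is.na(idx["id"])) df[[idx["id"]]] else seq_len(nrow(df))
  if (anyDuplicated(ids))
    stop(sprintf("duplicate ids: '%s'", ids[anyDuplicated(ids)]))

  out <- list(points = coords, ids = ids)
  for (role in c("volume", "intensity")) {
    if (!is.na(idx[role])) out[[role]] <- as.numeric(df[[idx[role]]])
  }
  if (!is.na(idx["truth"])) {
    truth <- as.integer(df[[idx["truth"]]])
    if (length(truth) && !all(truth %in% 0:1))
      stop("`truth` column must contain only bits 0 (inside) / 1 (outside)")
    out$truth <- truth
  }
  class(out) <- c(if (!is.null(out$truth)) "labelled_shape", "centroid_table")
  out
}

#' Write classification results
#'
#' Writes a CSV with one row per point: `id`, `x`, `y`, `z`, the predicted
#' `label` (0 = inside, 1 = outside) and, when ground truth is available,
#' the `truth` bit and the four-way `designation` string. The file
#' round-trips through [read_centroids()] (map `truth = "label"` to recover
#' the predicted labels).
#'
#' @param result An `io_classification` (carrying `points` and `labels`).
#' @param path Output file path.
#' @param ids Optional point ids (default `1:n`).
#' @param truth Optional ground-truth bits; when given, designations from
#'   [designate()] are added.
#' @return The output path, invisibly.
#' @export
write_results <- function(result, path, ids = NULL, truth = NULL) {
  if (!inherits(result, "io_classification") || is.null(result$points))
    stop("`result` must be an io_classification carrying its points")
  n <- length(result$labels)
  df <- data.frame(id = ids %||% seq_len(n))
  if (n > 0L) {
    df$x <- result$points[, 1L]
    df$y <- result$points[, 2L]
    df$z <- result$points[, 3L]
  } else {
    df <- data.frame(id = integer(0), x = numeric(0), y = numeric(0), z = numeric(0))
  }
  df$label <- result$labels
  if (!is.null(truth)) {
    df$truth <- as.integer(truth)
    df$designation <- as.character(designate(truth, result$labels))
  }
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Command-line interface
#'
#' A small CLI over the package's classifiers, simulator and sweep
#' experiments, suitable for wrapping in an Rscript launcher (one is
#' shipped at `system.file("cli", "insideoutside.R", package =
#' "insideOutside")`). Subcommands:
#' \describe{
#'   \item{`classify`}{`--input table.csv --out labels.csv
#'     [--method insideoutside|convexhull|ellipsoid-naive|ellipsoid-ransac]
#'     [--epsilon 0.01] [--clustering hierarchical] [--transform log10]
#'     [--threshold 0.95] [--seed N]`}
#'   \item{`simulate`}{`--out shape.csv [--n-outside 100] [--n-inside 50]
#'     [--inner-radius 0.5] [--outer-radius 1] [--noise-factor 0]
#'     [--seed N]` -- writes an x,y,z,truth fixture.}
#'   \item{`sweep`}{`--type radius|epsilon|noise --out sweep.csv
#'     [--radii 0.1,0.5,1] [--epsilons 0.001,0.01,0.1]
#'     [--noise-factors 0,0.1] [--replicates 100] [--seed N]` -- writes a
#'     tidy CSV of mean/sd rates.}
#'   \item{`benchmark`}{`--input labelled.csv | --inner-radius R
#'     [--noise-factor F] [--replicates N] [--seed N] [--out rates.csv]` --
#'     per-method rate table on a labelled input or simulated shapes.}
#' }
#' Every run logs the package version, the parsed configuration, the seed
#' and the runtime to standard error, so outputs are attributable and
#' reproducible: identical command + seed gives identical files.
#'
#' @param args Character vector of command-line arguments (default: the
#'   actual command line).
#' @return The exit code, invisibly: 0 on success, non-zero on a usage
#'   error.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  t0 <- Sys.time()
  usage <- function() {
    message("usage: insideoutside <classify|simulate|sweep|benchmark> [--flag value ...]")
    message("see ?insideOutside::cli_main for the full flag list")
  }
  if (length(args) == 0L) { usage(); return(invisible(1L)) }
  cmd <- args[[1L]]
  if (!cmd %in% c("classify", "simulate", "sweep", "benchmark")) {
    message(sprintf("unknown subcommand '%s'", cmd)); usage(); return(invisible(1L))
  }
  opts <- tryCatch(parse_flags(args[-1L]),
                   error = function(e) { message(conditionMessage(e)); NULL })
  if (is.null(opts)) { usage(); return(invisible(1L)) }

  status <- tryCatch({
    switch(cmd,
           classify = cli_classify(opts),
           simulate = cli_simulate(opts),
           sweep = cli_sweep(opts),
           benchmark = cli_benchmark(opts))
    0L
  }, error = function(e) { message("error: ", conditionMessage(e)); 1L })

  message(sprintf("insideOutside %s | %s | seed=%s | %s | %.2fs",
                  as.character(packageVersion("insideOutside")), cmd,
                  opts$seed %||% "none",
                  paste(sprintf("%s=%s", names(opts), unlist(opts)), collapse = " "),
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  invisible(status)
}

# "--some-flag value" pairs -> list(some_flag = "value")
parse_flags <- function(args) {
  if (length(args) %% 2L != 0L) stop("flags must come in '--name value' pairs")
  opts <- list()
  for (i in seq(1L, length(args), by = 2L)) {
    flag <- args[[i]]
    if (!startsWith(flag, "--")) stop(sprintf("expected a --flag, got '%s'", flag))
    opts[[gsub("-", "_", substring(flag, 3L))]] <- args[[i + 1L]]
  }
  opts
}

opt_num <- function(opts, name, default = NULL) {
  if (is.null(opts[[name]])) return(default)
  as.numeric(opts[[name]])
}

opt_num_vec <- function(opts, name, default = NULL) {
  if (is.null(opts[[name]])) return(default)
  as.numeric(strsplit(opts[[name]], ",")[[1L]])
}

opt_seed <- function(opts) {
  if (is.null(opts$seed)) NULL else as.integer(opts$seed)
}

cli_config <- function(opts) {
  io_config(
    epsilon = opt_num(opts, "epsilon", 0.01),
    transform = opts$transform %||% "log10",
    clustering = opts$clustering %||% "hierarchical",
    feature_mode = opts$feature_mode %||% "bivariate",
    seed = opt_seed(opts)
  )
}

cli_classify <- function(opts) {
  if (is.null(opts$input) || is.null(opts$out))
    stop("classify needs --input and --out")
  tab <- read_centroids(opts$input)
  method <- opts$method %||% "insideoutside"
  cfg <- cli_config(opts)
  labels <- classify_by_method(tab$points, method, cfg,
                               ransac_config(seed = opt_seed(opts)))
  res <- structure(list(labels = labels, method = method, points = tab$points),
                   class = "io_classification")
  write_results(res, opts$out, ids = tab$ids, truth = tab$truth)
  invisible(opts$out)
}

cli_simulate <- function(opts) {
  if (is.null(opts$out)) stop("simulate needs --out")
  spec <- shape_spec(
    n_outside = opt_num(opts, "n_outside", 100),
    n_inside = opt_num(opts, "n_inside", 50),
    inner_radius = opt_num(opts, "inner_radius", 0.5),
    outer_radius = opt_num(opts, "outer_radius", 1),
    noise_factor = opt_num(opts, "noise_factor", 0),
    seed = opt_seed(opts)
  )
  shape <- make_test_shape(spec)
  df <- data.frame(id = seq_along(shape$truth),
                   x = shape$points[, 1L], y = shape$points[, 2L],
                   z = shape$points[, 3L], truth = shape$truth)
  write.csv(df, opts$out, row.names = FALSE, quote = FALSE)
  invisible(opts$out)
}

cli_sweep <- function(opts) {
  if (is.null(opts$type) || is.null(opts$out))
    stop("sweep needs --type (radius|epsilon|noise) and --out")
  reps <- as.integer(opt_num(opts, "replicates", 100))
  radii <- opt_num_vec(opts, "radii", seq(0.1, 1, by = 0.1))
  cfg <- cli_config(opts)
  sw <- switch(opts$type,
    radius = radius_sweep(radii, reps, cfg, seed = opt_seed(opts)),
    epsilon = epsilon_sweep(radii, opt_num_vec(opts, "epsilons", c(0.001, 0.01, 0.1)),
                            reps, cfg, seed = opt_seed(opts)),
    noise = noise_sweep(radii, opt_num_vec(opts, "noise_factors", seq(0, 0.25, by = 0.05)),
                        n_replicates = reps, config = cfg, seed = opt_seed(opts)),
    stop(sprintf("unknown sweep type '%s'", opts$type))
  )
  write.csv(as.data.frame(sw), opts$out, row.names = FALSE, quote = FALSE)
  invisible(opts$out)
}

cli_benchmark <- function(opts) {
  cfg <- cli_config(opts)
  if (!is.null(opts$input)) {
    shape <- read_centroids(opts$input)
    if (is.null(shape$truth)) stop("benchmark --input needs a truth column")
    tab <- benchmark_methods(shape, config = cfg)
  } else {
    reps <- as.integer(opt_num(opts, "replicates", 20))
    spec <- shape_spec(inner_radius = opt_num(opts, "inner_radius", 0.5),
                       noise_factor = opt_num(opts, "noise_factor", 0))
    seeds <- draw_seeds(reps, opt_seed(opts))
    runs <- lapply(seeds, function(s) {
      spec$seed <- s
      benchmark_methods(make_test_shape(spec), config = cfg)
    })
    all <- do.call(rbind, runs)
    tab <- do.call(rbind, lapply(split(all, all$method), function(d) {
      data.frame(method = d$method[1L],
                 true_inside = mean(d$true_inside),
                 true_outside = mean(d$true_outside), n = nrow(d))
    }))
    rownames(tab) <- NULL
  }
  if (!is.null(opts$out)) {
    write.csv(tab, opts$out, row.names = FALSE, quote = FALSE)
  } else {
    print(tab)
  }
  invisible(tab)
}
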