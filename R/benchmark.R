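# Degrade-then-interpolate benchmark harness: every reference image is
# downscaled to 50% by nearest-neighbour replication, re-interpolated with
# each method, and scored against the original with the full metric suite.
# Aggregates are reported as mean +/- sd per method (the usual comparison-
# table layout; the feature-similarity column of that layout is out of
# scope here and omitted with this note).

BENCHMARK_METHODS <- c("nearest", "bilinear", "bicubic", "nedi", "cem", "tedi")

#' Benchmark configuration
#'
#' @param methods subset of
#'   `c("nearest", "bilinear", "bicubic", "nedi", "cem", "tedi")`.
#' @param corpus `NULL` for the default corpus (12 phantoms of 360 x 320,
#'   seed 2013, echoing the 12-image clinical set and its region-of-
#'   interest size), a list of [gray_image]s, or a directory of PNG/TIFF
#'   files.
#' @param factor magnification factor, 2 (quantitative protocol) or 4
#'   (visual protocol); the degrade step is always 50%.
#' @param output optional CSV path passed to [write_metric_report()].
#' @param seed corpus seed (all randomness flows from here).
#' @param corpus_n,corpus_size default-corpus shape.
#' @param tedi,nedi optional [tedi_config()] / [nedi_config()] overrides.
#' @return A list of class `benchmark_config`.
#' @export
benchmark_config <- function(methods = c("nearest", "bilinear", "bicubic",
                                         "nedi", "tedi"),
                             corpus = NULL, factor = 2L, output = NULL,
                             seed = 2013L, corpus_n = 12L,
                             corpus_size = c(360L, 320L),
                             tedi = NULL, nedi = NULL) {
  methods <- match.arg(methods, BENCHMARK_METHODS, several.ok = TRUE)
  factor <- as.integer(factor)
  if (!factor %in% c(2L, 4L)) stop("factor must be 2 or 4")
  if (factor == 4L && !is.null(nedi) && nedi$levels != 2L) {
    stop("factor 4 requires nedi levels = 2")
  }
  structure(list(methods = methods, corpus = corpus, factor = factor,
                 output = output, seed = as.integer(seed),
                 corpus_n = as.integer(corpus_n),
                 corpus_size = as.integer(corpus_size),
                 tedi = tedi, nedi = nedi),
            class = "benchmark_config")
}

resolve_corpus <- function(config) {
  corpus <- config$corpus
  if (is.null(corpus)) {
    return(make_corpus(config$corpus_n, config$corpus_size, config$seed))
  }
  if (is.character(corpus)) {
    files <- sort(list.files(corpus, pattern = "\\.(png|tif|tiff)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (length(files) == 0) stop("no PNG/TIFF images found in ", corpus)
    imgs <- lapply(files, read_image)
    names(imgs) <- basename(files)
    return(imgs)
  }
  if (is.list(corpus)) return(corpus)
  stop("corpus must be NULL, a directory path, or a list of images")
}

interpolate_by <- function(method, lr, factor, config) {
  switch(method,
    nearest = resample(lr, factor, "nearest"),
    bilinear = resample(lr, factor, "bilinear"),
    bicubic = resample(lr, factor, "bicubic"),
    nedi = {
      cfg <- if (is.null(config$nedi)) nedi_config() else config$nedi
      cfg$levels <- as.integer(round(log2(factor)))
      nedi_interpolate(lr, cfg)
    },
    cem = cem_interpolate(lr, factor),
    tedi = {
      cfg <- if (is.null(config$tedi)) tedi_config() else config$tedi
      cfg$factor <- factor
      tedi_interpolate(lr, cfg)
    },
    stop("unknown method: ", method))
}

#' Run the degrade-then-interpolate benchmark
#'
#' For every corpus image: crop to a size divisible by `2 * factor`,
#' degrade to 50% ([degrade()]), interpolate back with each method, and
#' score against the original ([evaluate_pair()]). Deterministic given the
#' seed, except for the wall-clock `tc_seconds` column (measured around the
#' interpolation call only).
#'
#' @param config a [benchmark_config()].
#' @return A list of class `metric_report` with `rows` (one per
#'   method x image) and `aggregates` (per-method mean/sd, see
#'   [aggregate_metrics()]). Written to CSV when `config$output` is set.
#' @export
run_benchmark <- function(config = benchmark_config()) {
  stopifnot(inherits(config, "benchmark_config"))
  corpus <- resolve_corpus(config)
  if (length(corpus) == 0) stop("empty corpus")
  ids <- names(corpus)
  if (is.null(ids)) ids <- sprintf("phantom_%02d", seq_along(corpus))
  rows <- list()
  for (i in seq_along(corpus)) {
    ref <- crop_multiple(corpus[[i]], 2L * config$factor)
    lr <- degrade(ref)
    target <- if (config$factor == 2L) {
      ref
    } else {
      crop_multiple(resample(ref, config$factor / 2, "bilinear"), 1L)
    }
    for (method in config$methods) {
      t0 <- proc.time()[["elapsed"]]
      hr <- interpolate_by(method, lr, config$factor, config)
      elapsed <- proc.time()[["elapsed"]] - t0
      cmp_ref <- if (config$factor == 2L) ref else target
      rows[[length(rows) + 1L]] <-
        evaluate_pair(cmp_ref, hr, method, ids[i], elapsed)
    }
  }
  rows <- do.call(rbind, rows)
  report <- structure(list(rows = rows, aggregates = aggregate_metrics(rows),
                           factor = config$factor, seed = config$seed),
                      class = "metric_report")
  if (!is.null(config$output)) write_metric_report(report, config$output)
  report
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("<metric_report: %d rows, factor %d>\n", nrow(x$rows), x$factor))
  agg <- x$aggregates
  for (m in unique(agg$method)) {
    a <- agg[agg$method == m, ]
    cat(sprintf("  %-8s PSNR %6.2f ± %4.2f  SSIM %5.3f ± %5.3f  MI %5.2f ± %4.2f\n",
                m,
                a$mean[a$metric == "psnr_db"], a$sd[a$metric == "psnr_db"],
                a$mean[a$metric == "ssim"], a$sd[a$metric == "ssim"],
                a$mean[a$metric == "mi_bits"], a$sd[a$metric == "mi_bits"]))
  }
  invisible(x)
}
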