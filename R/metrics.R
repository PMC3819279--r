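# Full-reference image quality metrics: SNR, PSNR, SSIM, mutual
# information, plus report assembly with mean +/- sd aggregation.
#
# Identical image pairs give infinite SNR/PSNR; the CSV writer serializes
# these as the string "inf" and aggregation excludes non-finite values
# (with a note), so a perfect reconstruction cannot silently dominate a
# mean.

#' Signal-to-noise ratio in dB
#'
#' `10 log10( sum(ref^2) / sum((ref - test)^2) )`; `Inf` for identical
#' images. Invariant under common rescaling of both images.
#'
#' @param ref,test [gray_image]s or matrices with identical dims.
#' @return SNR in dB (possibly `Inf`).
#' @export
snr <- function(ref, test) {
  r <- as_pixels(ref)
  t <- as_pixels(test)
  stop_if_dim_mismatch(r, t)
  err <- sum((r - t)^2)
  if (err == 0) return(Inf)
  10 * log10(sum(r^2) / err)
}

#' Peak signal-to-noise ratio in dB
#'
#' `10 log10( peak^2 / MSE )`; `Inf` for identical images. On the internal
#' normalized scale the native peak (255 or 65535) maps to `peak = 1`.
#'
#' @param ref,test [gray_image]s or matrices with identical dims.
#' @param peak dynamic range of the data (default 1 on the normalized scale).
#' @return PSNR in dB (possibly `Inf`).
#' @export
psnr <- function(ref, test, peak = 1) {
  r <- as_pixels(ref)
  t <- as_pixels(test)
  stop_if_dim_mismatch(r, t)
  if (peak <= 0) stop("peak must be positive")
  mse <- mean((r - t)^2)
  if (mse == 0) return(Inf)
  10 * log10(peak^2 / mse)
}

#' Mean structural similarity index (SSIM)
#'
#' The canonical construction: local means, variances and covariance are
#' computed with an 11 x 11 Gaussian window (sigma 1.5), combined with
#' stability constants `C1 = (K1 L)^2`, `C2 = (K2 L)^2`, `K1 = 0.01`,
#' `K2 = 0.03` on dynamic range `L`. The 5-pixel border, where the window
#' would overhang the image, is excluded from the mean, so padding plays no
#' role.
#'
#' @param ref,test [gray_image]s or matrices with identical dims, each at
#'   least 11 x 11.
#' @param data_range dynamic range `L` (default 1).
#' @return Mean SSIM in `[-1, 1]`; 1 iff the images are identical.
#' @export
ssim <- function(ref, test, data_range = 1) {
  x <- as_pixels(ref)
  y <- as_pixels(test)
  stop_if_dim_mismatch(x, y)
  if (nrow(x) < 11 || ncol(x) < 11) {
    stop("SSIM requires images of at least 11 x 11")
  }
  g <- gaussian_kernel(1.5, radius = 5L)
  f <- function(m) conv_sep_replicate(m, g, g)
  c1 <- (0.01 * data_range)^2
  c2 <- (0.03 * data_range)^2
  mx <- f(x)
  my <- f(y)
  vx <- f(x * x) - mx^2
  vy <- f(y * y) - my^2
  cxy <- f(x * y) - mx * my
  map <- ((2 * mx * my + c1) * (2 * cxy + c2)) /
    ((mx^2 + my^2 + c1) * (vx + vy + c2))
  core <- map[6:(nrow(x) - 5), 6:(ncol(x) - 5)]
  mean(core)
}

#' Mutual information between two images, in bits
#'
#' MI of the joint intensity histogram over `bins` equal-width bins on
#' `[0, 1]`, using base-2 logarithms. `mutual_information(x, x)` equals the
#' marginal histogram entropy `H(x)` at the same binning; independent
#' images give values near 0.
#'
#' @param ref,test [gray_image]s or matrices with identical dims.
#' @param bins number of histogram bins, `>= 2` (default 256).
#' @return Non-negative mutual information in bits.
#' @export
mutual_information <- function(ref, test, bins = 256L) {
  x <- as_pixels(ref)
  y <- as_pixels(test)
  stop_if_dim_mismatch(x, y)
  bins <- as.integer(bins)
  if (is.na(bins) || bins < 2) stop("bins must be an integer >= 2")
  ix <- pmin(floor(as.vector(x) * bins), bins - 1L)
  iy <- pmin(floor(as.vector(y) * bins), bins - 1L)
  joint <- tabulate(ix * bins + iy + 1L, nbins = bins * bins)
  n <- length(ix)
  pj <- joint / n
  pm <- matrix(pj, bins, bins)  # columns indexed by ix, rows by iy
  px <- colSums(pm)
  py <- rowSums(pm)
  nz <- which(pm > 0, arr.ind = TRUE)
  p <- pm[nz]
  sum(p * log2(p / (px[nz[, 2]] * py[nz[, 1]])))
}

#' Measure the 10-90% edge transition width
#'
#' Sharpness diagnostic for step-edge images: the intensity profile is
#' sampled (bilinearly, step 0.1 px) along the gradient direction through a
#' given point, and the width is the distance between the first crossings
#' of the 10% and 90% levels of the `lo`-`hi` transition around that point.
#' Smaller is sharper; an ideal step has width ~1 px after anti-aliasing.
#'
#' @param img [gray_image] or matrix.
#' @param angle edge line angle in degrees (the gradient direction is
#'   `angle + 90`), as in the `oriented_step` phantom.
#' @param center `c(row, col)` of the profile center; defaults to the image
#'   center.
#' @param lo,hi the two step levels (defaults 0.2 / 0.8).
#' @param halfspan profile half-length in pixels (default 8).
#' @return Transition width in pixels (`NA` if the levels are not crossed).
#' @export
edge_transition_width <- function(img, angle, center = NULL,
                                  lo = 0.2, hi = 0.8, halfspan = 8) {
  pixels <- as_pixels(img)
  h <- nrow(pixels)
  w <- ncol(pixels)
  if (is.null(center)) center <- c((h + 1) / 2, (w + 1) / 2)
  theta <- angle * pi / 180
  # unit vector along the gradient (normal to the edge line), image coords
  gdir <- c(-cos(theta), sin(theta))  # (drow, dcol)
  s <- seq(-halfspan, halfspan, by = 0.1)
  rr <- pmin(pmax(center[1] + s * gdir[1], 1), h)
  cc <- pmin(pmax(center[2] + s * gdir[2], 1), w)
  r0 <- pmin(floor(rr), h - 1)
  c0 <- pmin(floor(cc), w - 1)
  fr <- rr - r0
  fc <- cc - c0
  prof <- (1 - fr) * ((1 - fc) * pixels[cbind(r0, c0)] + fc * pixels[cbind(r0, c0 + 1)]) +
    fr * ((1 - fc) * pixels[cbind(r0 + 1, c0)] + fc * pixels[cbind(r0 + 1, c0 + 1)])
  if (prof[1] > prof[length(prof)]) prof <- rev(prof)
  t10 <- lo + 0.1 * (hi - lo)
  t90 <- lo + 0.9 * (hi - lo)
  i10 <- which(prof >= t10)[1]
  i90 <- which(prof >= t90)[1]
  if (is.na(i10) || is.na(i90) || i90 <= i10) return(NA_real_)
  0.1 * (i90 - i10)
}

# marginal histogram entropy in bits at the same binning as MI
shannon_entropy <- function(img, bins = 256L) {
  x <- as_pixels(img)
  ix <- pmin(floor(as.vector(x) * bins), bins - 1L)
  p <- tabulate(ix + 1L, nbins = bins) / length(ix)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Assemble one benchmark report row
#'
#' @param ref,test [gray_image]s or matrices with identical dims.
#' @param method_name method label for the row.
#' @param image_id image label for the row.
#' @param elapsed wall-clock seconds of the interpolation call (`>= 0`);
#'   hardware-dependent and never asserted in tests.
#' @return A one-row `data.frame` with columns `method`, `image_id`,
#'   `snr_db`, `psnr_db`, `ssim`, `mi_bits`, `tc_seconds`.
#' @export
evaluate_pair <- function(ref, test, method_name, image_id = "img",
                          elapsed = NA_real_) {
  if (!is.na(elapsed) && elapsed < 0) stop("elapsed must be >= 0")
  data.frame(method = method_name,
             image_id = image_id,
             snr_db = snr(ref, test),
             psnr_db = psnr(ref, test),
             ssim = ssim(ref, test),
             mi_bits = mutual_information(ref, test),
             tc_seconds = elapsed,
             stringsAsFactors = FALSE)
}

#' Aggregate per-image metric rows into per-method mean and sd
#'
#' Non-finite values (the infinite-SNR sentinel of identical pairs) are
#' excluded from aggregation; the number of finite rows used is reported in
#' `n_used` per metric.
#'
#' @param rows `data.frame` of [evaluate_pair()] rows.
#' @return Long-format `data.frame(method, metric, mean, sd, n_used)`.
#' @export
aggregate_metrics <- function(rows) {
  metrics <- c("snr_db", "psnr_db", "ssim", "mi_bits", "tc_seconds")
  out <- do.call(rbind, lapply(split(rows, rows$method), function(d) {
    do.call(rbind, lapply(metrics, function(m) {
      v <- d[[m]]
      v <- v[is.finite(v)]
      data.frame(method = d$method[1], metric = m,
                 mean = if (length(v)) mean(v) else NA_real_,
                 sd = if (length(v) > 1) sd(v) else NA_real_,
                 n_used = length(v),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Write a benchmark report as CSV
#'
#' Writes the per-image rows to `path` and the aggregate block (one line
#' per method and metric, with a `formatted` column `"mean ± sd"`) to
#' `<path stem>_aggregate.csv`. Infinite values are serialized as the
#' string `"inf"`.
#'
#' @param report a `metric_report` from [run_benchmark()], or a list with
#'   elements `rows` and `aggregates`.
#' @param path output CSV path for the per-image rows.
#' @return Invisibly, a character vector of the two paths written.
#' @export
write_metric_report <- function(report, path) {
  rows <- report$rows
  for (m in c("snr_db", "psnr_db")) {
    rows[[m]] <- ifelse(is.infinite(rows[[m]]), "inf",
                        format(rows[[m]], digits = 10))
  }
  write.csv(rows, path, row.names = FALSE)
  agg <- report$aggregates
  agg$formatted <- sprintf("%.2f ± %.2f", agg$mean, agg$sd)
  agg_path <- file.path(dirname(path),
                        paste0(tools::file_path_sans_ext(basename(path)),
                               "_aggregate.csv"))
  write.csv(agg, agg_path, row.names = FALSE)
  invisible(c(path, agg_path))
}
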