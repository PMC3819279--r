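#' Resample an image by a scale factor
#'
#' Classical resamplers used both as pre-interpolators and as baselines.
#' For integer factors `k >= 1` the grid is corner-anchored: low-resolution
#' pixel `(i, j)` maps exactly onto high-resolution pixel `(k i, k j)`
#' (0-based), which gives every LR edge point a well-defined HR position.
#' Fractional factors use center-aligned continuous coordinates. Nearest
#' neighbour is pixel replication (`src = floor(dst / factor)`); at factor
#' 0.5 it keeps the top-left sample of each 2 x 2 block. Out-of-range reads
#' are edge-clamped and bilinear/bicubic output is clipped to `[0, 1]`.
#'
#' @param img a [gray_image] or numeric matrix in `[0, 1]`.
#' @param factor positive scale factor; output dims are
#'   `round(factor * dim)`, each at least 1.
#' @param method one of `"nearest"`, `"bilinear"`, `"bicubic"`
#'   (Keys kernel, a = -0.5).
#' @return A [gray_image] of the scaled size (same `source_depth`).
#' @examples
#' img <- gray_image(matrix(runif(64), 8, 8))
#' dim(resample(img, 2, "bilinear"))
#' @export
resample <- function(img, factor, method = c("bilinear", "nearest", "bicubic")) {
  method <- match.arg(method)
  if (!is.numeric(factor) || length(factor) != 1 || !is.finite(factor) ||
      factor <= 0) {
    stop("factor must be a positive number")
  }
  pixels <- as_pixels(img)
  out_h <- max(1L, as.integer(round(factor * nrow(pixels))))
  out_w <- max(1L, as.integer(round(factor * ncol(pixels))))
  method_id <- match(method, c("nearest", "bilinear", "bicubic")) - 1L
  corner <- isTRUE(all.equal(factor, round(factor))) && factor >= 1
  out <- resample_grid(pixels, out_h, out_w, factor, method_id, corner)
  depth <- if (inherits(img, "gray_image")) img$source_depth else 8L
  gray_image(out, source_depth = depth)
}
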