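#' Build the 5 x 5 orientation-specific blending mask
#'
#' The sharpening filter applied at true edge pixels. In the 5 x 5
#' neighbourhood of an edge point only three entries are non-zero: the
#' center, weighted `ratio`, and the two symmetric along-edge offsets, each
#' weighted `sqrt(ratio)`; the mask is then normalized to sum 1. For a
#' left-vertical (LV) edge the along-edge offsets are `(-1, -2)` and
#' `(+1, +2)` (row, column); the other three orientations are the symmetry
#' images of the LV mask:
#' \itemize{
#'   \item RH: offsets `(-2, -1)`, `(+2, +1)` (transpose, reflection about 45 deg)
#'   \item RV: offsets `(-1, +2)`, `(+1, -2)` (column mirror, reflection about 90 deg)
#'   \item LH: offsets `(-2, +1)`, `(+2, -1)`
#' }
#' Each mask averages along the edge line implied by its gradient bin, so
#' larger `ratio` means less along-edge smoothing (the mask tends to a
#' delta); `ratio = 1` is a uniform 3-point along-edge average. The default
#' used throughout the package is `ratio = 4`, the plateau of the
#' SNR-versus-ratio sweep (see [calibrate_ratio()]): pre-normalization
#' weights `{4, 2, 2}`, normalized `{0.5, 0.25, 0.25}`.
#'
#' @param orientation one of `"RH"`, `"LV"`, `"RV"`, `"LH"`.
#' @param ratio center emphasis, `>= 1`.
#' @return An object of class `blend_mask`: list with `weights` (5 x 5,
#'   summing to 1), `offsets` (2 x 2 matrix of the along-edge offsets),
#'   `orientation` and `ratio`.
#' @examples
#' build_blend_mask("LV", 4)$weights
#' @export
build_blend_mask <- function(orientation, ratio) {
  orientation <- match.arg(orientation, ORIENTATION_LEVELS[-1L])
  if (!is.numeric(ratio) || length(ratio) != 1 || !is.finite(ratio) ||
      ratio < 1) {
    stop("ratio must be a number >= 1")
  }
  off <- blend_offsets(orientation)
  w <- matrix(0, 5, 5)
  w[3, 3] <- ratio
  w[3 + off[1, 1], 3 + off[1, 2]] <- sqrt(ratio)
  w[3 + off[2, 1], 3 + off[2, 2]] <- sqrt(ratio)
  structure(list(weights = w / sum(w), offsets = off,
                 orientation = orientation, ratio = ratio),
            class = "blend_mask")
}

# along-edge (row, col) offsets for each orientation bin
blend_offsets <- function(orientation) {
  o <- switch(orientation,
              LV = c(-1L, -2L),
              RH = c(-2L, -1L),
              RV = c(-1L, 2L),
              LH = c(-2L, 1L))
  rbind(o, -o, deparse.level = 0)
}

#' @export
print.blend_mask <- function(x, ...) {
  cat(sprintf("<blend_mask %s, ratio %.3g>\n", x$orientation, x$ratio))
  print(round(x$weights, 4))
  invisible(x)
}
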