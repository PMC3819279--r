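#' Grayscale image container
#'
#' The universal currency of the package: a 2-D grid of intensities stored as
#' doubles normalized to `[0, 1]`, together with the native bit depth of the
#' file it came from (used when writing back to disk). All algorithmic
#' operations require at least a 3 x 3 grid.
#'
#' @param pixels numeric matrix of intensities in `[0, 1]` (rows = image rows).
#' @param source_depth native depth of the originating file, 8 or 16 (bits).
#' @return An object of class `gray_image`.
#' @examples
#' img <- gray_image(matrix(seq(0, 1, length.out = 64), 8, 8))
#' dim(img)
#' @export
gray_image <- function(pixels, source_depth = 8L) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("pixels must be a numeric matrix")
  }
  storage.mode(pixels) <- "double"
  if (any(!is.finite(pixels))) stop("pixels must be finite")
  if (min(pixels) < 0 || max(pixels) > 1) {
    stop("pixels must lie in [0, 1]; rescale before constructing")
  }
  source_depth <- as.integer(source_depth)
  if (!source_depth %in% c(8L, 16L)) stop("source_depth must be 8 or 16")
  structure(list(pixels = pixels,
                 height = nrow(pixels),
                 width = ncol(pixels),
                 source_depth = source_depth),
            class = "gray_image")
}

#' @export
dim.gray_image <- function(x) dim(x$pixels)

#' @export
as.matrix.gray_image <- function(x, ...) x$pixels

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image %d x %d, %d-bit source, range [%.3f, %.3f]>\n",
              x$height, x$width, x$source_depth,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @method all.equal gray_image
#' @export
all.equal.gray_image <- function(target, current, ...) {
  all.equal(target$pixels, current$pixels, ...)
}

# coerce matrices / gray_image to a plain pixel matrix
as_pixels <- function(x) {
  if (inherits(x, "gray_image")) return(x$pixels)
  if (is.matrix(x) && is.numeric(x)) return(x)
  stop("expected a gray_image or numeric matrix")
}

check_min_size <- function(img, min_dim = 3L) {
  d <- dim(as_pixels(img))
  if (any(d < min_dim)) {
    stop("image must be at least ", min_dim, "x", min_dim, ", got ",
         paste(d, collapse = "x"))
  }
  invisible(TRUE)
}
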