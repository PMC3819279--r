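# Seeded synthetic phantoms. The clinical images the degrade-then-restore
# protocol was designed around are confidential, so every test and benchmark
# in this package runs on edge-rich synthetic images instead: oriented step
# edges, disks, rings, gratings, checkerboards, smooth blob fields, and a
# stylized "spine band" (a bright curved band fading from bright to dark on
# a dark background). Phantoms are pure functions of their spec.

PHANTOM_KINDS <- c("oriented_step", "disk", "ring", "grating", "checker",
                   "blob_field", "spine_band")

#' Specify a synthetic phantom image
#'
#' @param kind one of `"oriented_step"`, `"disk"`, `"ring"`, `"grating"`,
#'   `"checker"`, `"blob_field"`, `"spine_band"`.
#' @param size `c(height, width)`, each at least 16.
#' @param params kind-specific parameter list; unknown entries are an
#'   error. Common entries: `lo`, `hi` (intensity levels), `angle`
#'   (degrees), `radius`, `inner`/`outer`, `frequency` (cycles across the
#'   image), `block` (checker block side), `n_blobs`, `amplitude`
#'   (band curvature), `binary` (disable the 1-pixel anti-aliased boundary).
#' @param noise_sigma additive Gaussian noise sd on the `[0, 1]` scale,
#'   `0 <= noise_sigma < 0.5`.
#' @param seed integer seed; identical specs give bit-identical images.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(kind, size = c(64L, 64L), params = list(),
                         noise_sigma = 0, seed = 1L) {
  kind <- match.arg(kind, PHANTOM_KINDS)
  size <- as.integer(size)
  if (length(size) != 2 || any(size < 16)) {
    stop("size must be c(height, width) with both >= 16")
  }
  if (noise_sigma < 0 || noise_sigma >= 0.5) {
    stop("noise_sigma must lie in [0, 0.5)")
  }
  structure(list(kind = kind, size = size, params = params,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "phantom_spec")
}

param <- function(spec, name, default) {
  v <- spec$params[[name]]
  if (is.null(v)) default else v
}

#' Generate a phantom image from its spec
#'
#' Deterministic per spec (all randomness flows from `spec$seed` and the
#' global RNG state is restored afterwards). Step-like phantoms get a
#' 1-pixel anti-aliased boundary by default so the edge detector has a
#' localizable gradient maximum; pass `params = list(binary = TRUE)` for
#' hard steps.
#'
#' @param spec a [phantom_spec()].
#' @return A [gray_image].
#' @examples
#' img <- make_phantom(phantom_spec("oriented_step", c(32, 32),
#'                                  params = list(angle = 90)))
#' img$pixels[1, 1]; img$pixels[1, 32]
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  h <- spec$size[1]
  w <- spec$size[2]
  rc <- (h + 1) / 2
  cc <- (w + 1) / 2
  row <- matrix(seq_len(h), h, w) - rc   # signed row offset from center
  col <- matrix(seq_len(w), h, w, byrow = TRUE) - cc
  lo <- param(spec, "lo", 0.2)
  hi <- param(spec, "hi", 0.8)
  binary <- isTRUE(param(spec, "binary", FALSE))
  edge_profile <- function(s) {
    # signed distance -> two-level profile with 1-px anti-aliased boundary
    if (binary) lo + (hi - lo) * (s > 0) else lo + (hi - lo) * clip01(s + 0.5)
  }
  m <- switch(spec$kind,
    oriented_step = {
      # boundary line through the center at `angle` degrees from horizontal;
      # the brighter side is the one the line's right-hand normal points to
      theta <- param(spec, "angle", 90) * pi / 180
      s <- col * sin(theta) - row * cos(theta)
      edge_profile(s)
    },
    disk = {
      r <- param(spec, "radius", min(h, w) / 4)
      edge_profile(r - sqrt(row^2 + col^2))
    },
    ring = {
      inner <- param(spec, "inner", min(h, w) / 6)
      outer <- param(spec, "outer", min(h, w) / 3)
      d <- sqrt(row^2 + col^2)
      edge_profile(pmin(d - inner, outer - d))
    },
    grating = {
      freq <- param(spec, "frequency", 4)
      theta <- param(spec, "angle", 0) * pi / 180
      phase <- 2 * pi * freq * (col * cos(theta) + row * sin(theta)) / max(h, w)
      (lo + hi) / 2 + (hi - lo) / 2 * sin(phase)
    },
    checker = {
      b <- param(spec, "block", 8)
      odd <- (floor((row + rc - 1) / b) + floor((col + cc - 1) / b)) %% 2
      lo + (hi - lo) * odd
    },
    blob_field = {
      n <- param(spec, "n_blobs", 6)
      with_seed(spec$seed, {
        acc <- matrix(0, h, w)
        for (i in seq_len(n)) {
          br <- runif(1, 0.15, 0.85) * h - rc
          bc <- runif(1, 0.15, 0.85) * w - cc
          sg <- runif(1, 0.05, 0.15) * min(h, w)
          amp <- runif(1, 0.4, 1)
          acc <- acc + amp * exp(-((row - br)^2 + (col - bc)^2) / (2 * sg^2))
        }
        lo + (hi - lo) * acc / max(acc)
      })
    },
    spine_band = {
      # bright curved band on a dark background whose intensity fades from
      # bright at the top to dark at the bottom -- a stylized stand-in for
      # the cervical-spine geometry of the clinical images
      amp <- param(spec, "amplitude", 0.15) * w
      width_px <- param(spec, "band_width", 0.08) * min(h, w)
      center_col <- amp * sin(pi * (row + rc) / h)
      d <- col - center_col
      band <- exp(-d^2 / (2 * width_px^2))
      fade <- seq(1, 0.35, length.out = h)
      bg <- param(spec, "lo", 0.1)
      bg + (hi - bg) * band * matrix(fade, h, w)
    })
  if (spec$noise_sigma > 0) {
    m <- with_seed(spec$seed + 1L,
                   m + matrix(rnorm(h * w, sd = spec$noise_sigma), h, w))
  }
  gray_image(clip01(m))
}

#' Degrade an image by the benchmark protocol
#'
#' Nearest-neighbour pixel-replication downscale to 50% (top-left sample of
#' each 2 x 2 block; odd dimensions are floor-rounded). This is the
#' degradation applied to every reference image before re-interpolation in
#' the benchmark.
#'
#' @param img [gray_image] or matrix.
#' @return A [gray_image] of size `floor(dim / 2)`.
#' @export
degrade <- function(img) {
  pixels <- as_pixels(img)
  out_h <- nrow(pixels) %/% 2L
  out_w <- ncol(pixels) %/% 2L
  if (out_h < 8 || out_w < 8) stop("degraded image would be smaller than 8 x 8")
  depth <- if (inherits(img, "gray_image")) img$source_depth else 8L
  gray_image(resample_grid(pixels, out_h, out_w, 0.5, 0L, FALSE), depth)
}

#' Generate a reproducible corpus of phantoms
#'
#' Cycles through the phantom kinds in the fixed order
#' `oriented_step, disk, ring, grating, checker, blob_field, spine_band`
#' (image `i` gets kind `(i - 1) mod 7 + 1`), with seeded jitter of the
#' kind parameters and mild additive noise (sd 0.02 by default, a visually
#' plausible noise floor for the low-field MR images the benchmark
#' emulates). Reproducible from `(n, size, seed)`.
#'
#' @param n number of images, `>= 1`.
#' @param size `c(height, width)` of every image.
#' @param seed corpus seed; image `i` uses `seed + i`.
#' @param noise_sigma additive noise sd passed to every spec.
#' @return A list of `n` [gray_image]s; the specs used are attached as the
#'   `specs` attribute (the corpus manifest).
#' @export
make_corpus <- function(n, size = c(360L, 320L), seed = 2013L,
                        noise_sigma = 0.02) {
  n <- as.integer(n)
  if (is.na(n) || n < 1) stop("n must be an integer >= 1")
  specs <- lapply(seq_len(n), function(i) {
    kind <- PHANTOM_KINDS[(i - 1L) %% length(PHANTOM_KINDS) + 1L]
    jit <- with_seed(seed + i, runif(4))
    params <- switch(kind,
      oriented_step = list(angle = 180 * jit[1]),
      disk = list(radius = (0.15 + 0.2 * jit[1]) * min(size)),
      ring = list(inner = (0.1 + 0.08 * jit[1]) * min(size),
                  outer = (0.25 + 0.12 * jit[2]) * min(size)),
      grating = list(frequency = 3 + 5 * jit[1], angle = 180 * jit[2]),
      checker = list(block = round(8 + 16 * jit[1])),
      blob_field = list(n_blobs = 4 + floor(5 * jit[1])),
      spine_band = list(amplitude = 0.1 + 0.1 * jit[1],
                        band_width = 0.06 + 0.04 * jit[2]))
    phantom_spec(kind, size, params, noise_sigma = noise_sigma,
                 seed = seed + i)
  })
  corpus <- lapply(specs, make_phantom)
  attr(corpus, "specs") <- specs
  corpus
}
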