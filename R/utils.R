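# shared internal helpers

clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

# run `code` with a temporary RNG seed, restoring global RNG state afterwards
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# shift a matrix by (dr, dc) with replicate (edge-clamp) padding:
# out[r, c] = m[clamp(r + dr), clamp(c + dc)]
shift_replicate <- function(m, dr, dc) {
  h <- nrow(m)
  w <- ncol(m)
  ri <- pmin(pmax(seq_len(h) + dr, 1L), h)
  ci <- pmin(pmax(seq_len(w) + dc, 1L), w)
  m[ri, ci, drop = FALSE]
}

# pad a matrix by one ring of linear extrapolation on every side
pad_linear <- function(m) {
  h <- nrow(m)
  w <- ncol(m)
  m2 <- rbind(2 * m[1, ] - m[2, ], m, 2 * m[h, ] - m[h - 1, ])
  cbind(2 * m2[, 1] - m2[, 2], m2, 2 * m2[, w] - m2[, w - 1])
}

# normalized Gaussian kernel, radius = max(1, ceiling(3 sigma)) unless given
gaussian_kernel <- function(sigma, radius = NULL) {
  if (is.null(radius)) radius <- max(1L, ceiling(3 * sigma))
  x <- seq(-radius, radius)
  g <- exp(-x^2 / (2 * sigma^2))
  g / sum(g)
}

# derivative-of-Gaussian kernel scaled so a unit ramp has response 1
gaussian_deriv_kernel <- function(sigma, radius = NULL) {
  if (is.null(radius)) radius <- max(1L, ceiling(3 * sigma))
  x <- seq(-radius, radius)
  g <- exp(-x^2 / (2 * sigma^2))
  kd <- x * g
  kd / sum(x * kd)
}

stop_if_dim_mismatch <- function(a, b) {
  if (!identical(dim(a), dim(b))) {
    stop("dimension mismatch: ", paste(dim(a), collapse = "x"), " vs ",
         paste(dim(b), collapse = "x"), call. = FALSE)
  }
  invisible(TRUE)
}
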