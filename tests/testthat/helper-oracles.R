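# Independent brute-force oracles used by the unit and acceptance tests.
# These deliberately share no code with the package internals.

# Chebyshev-distance pseudo-edge split by exhaustive double loop
oracle_pseudo_split <- function(hr_edges, true_edges, tol) {
  ti <- which(true_edges, arr.ind = TRUE)
  out <- matrix(FALSE, nrow(hr_edges), ncol(hr_edges))
  for (p in which(hr_edges)) {
    r <- (p - 1) %% nrow(hr_edges) + 1
    c <- (p - 1) %/% nrow(hr_edges) + 1
    if (nrow(ti) == 0) {
      out[r, c] <- TRUE
    } else {
      d <- pmax(abs(ti[, 1] - r), abs(ti[, 2] - c))
      out[r, c] <- min(d) > tol
    }
  }
  out
}

# 8-neighbour mean with replicate padding, direct loops
oracle_neighbor_mean <- function(m, r, c) {
  h <- nrow(m); w <- ncol(m)
  acc <- 0
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    acc <- acc + m[min(max(r + dr, 1), h), min(max(c + dc, 1), w)]
  }
  acc / 8
}

# orientation-specific 3-tap weighted sum with replicate padding
oracle_sharpen_value <- function(m, r, c, offsets, ratio) {
  h <- nrow(m); w <- ncol(m)
  at <- function(rr, cc) m[min(max(rr, 1), h), min(max(cc, 1), w)]
  v <- ratio * at(r, c) +
    sqrt(ratio) * at(r + offsets[1, 1], c + offsets[1, 2]) +
    sqrt(ratio) * at(r + offsets[2, 1], c + offsets[2, 2])
  v / (ratio + 2 * sqrt(ratio))
}

# histogram entropy in bits (oracle for MI(x,x) = H(x))
oracle_entropy <- function(m, bins = 256L) {
  idx <- pmin(floor(as.vector(m) * bins), bins - 1L)
  p <- as.vector(table(factor(idx, levels = 0:(bins - 1L)))) / length(idx)
  p <- p[p > 0]
  -sum(p * log2(p))
}

# finite-difference gradient angle (y up), for edge-label cross-checks
oracle_gradient_angle <- function(m, r, c) {
  gx <- (m[r, c + 1] - m[r, c - 1]) / 2
  gy <- (m[r + 1, c] - m[r - 1, c]) / 2
  (atan2(-gy, gx) * 180 / pi) %% 180
}

# seeded random test image in [0, 1]
rand_image <- function(h, w, seed) {
  set.seed(seed)
  matrix(runif(h * w), h, w)
}

# smooth seeded image (random lowpass) so Canny finds extended structure
smooth_image <- function(h, w, seed) {
  set.seed(seed)
  m <- matrix(runif(h * w), h, w)
  k <- rep(1 / 5, 5)
  m <- t(apply(m, 1, function(x) stats::filter(x, k, circular = TRUE)))
  m <- apply(m, 2, function(x) stats::filter(x, k, circular = TRUE))
  m <- m - min(m)
  m / max(m)
}
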