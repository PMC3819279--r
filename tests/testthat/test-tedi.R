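# Blending masks, edge projection, true/pseudo split, refinement operators,
# and the full interpolation pipeline.

test_that("the LV mask carries the published {ratio, sqrt(ratio)} weights", {
  bm <- build_blend_mask("LV", 4.0)
  pre <- bm$weights * (4 + 2 * sqrt(4))  # un-normalize
  expect_equal(pre[3, 3], 4, tolerance = 1e-12)
  expect_equal(pre[3 - 1, 3 - 2], 2, tolerance = 1e-12)
  expect_equal(pre[3 + 1, 3 + 2], 2, tolerance = 1e-12)
  expect_equal(sum(pre != 0), 3)
  expect_equal(sum(bm$weights), 1, tolerance = 1e-12)
  expect_equal(bm$weights[bm$weights != 0], c(0.25, 0.5, 0.25),
               tolerance = 1e-12)
})

test_that("ratio 1 gives a uniform 3-point along-edge average", {
  bm <- build_blend_mask("LV", 1.0)
  expect_equal(unique(bm$weights[bm$weights != 0]), 1 / 3, tolerance = 1e-12)
  expect_error(build_blend_mask("LV", 0.5), ">= 1")
})

test_that("the four masks are symmetry images of each other", {
  w <- lapply(c("RH", "LV", "RV", "LH"),
              function(o) build_blend_mask(o, 4)$weights)
  names(w) <- c("RH", "LV", "RV", "LH")
  expect_equal(w$RH, t(w$LV), tolerance = 1e-12)          # 45-deg reflection
  expect_equal(w$RV, w$LV[, 5:1], tolerance = 1e-12)      # column mirror
  expect_equal(w$LH, t(w$RV), tolerance = 1e-12)
  for (o in names(w)) expect_equal(sum(w[[o]] != 0), 3)
})

test_that("rotated step phantoms get the rotated mask with identical response", {
  # rotating the patch 90 deg clockwise turns an LV edge (gradient 45-90,
  # y up) into an LH edge (gradient 135-180): the LH mask applied to the
  # rotated patch must reproduce the LV response at the fixed center pixel
  set.seed(9)
  m <- matrix(runif(81), 9, 9)
  mask <- matrix(FALSE, 9, 9); mask[5, 5] <- TRUE
  orient_lv <- matrix(0L, 9, 9); orient_lv[5, 5] <- 2L   # LV
  out_lv <- sharpen_true_edges(m, mask, orient_lv, 4)
  rot <- t(m)[, 9:1]  # rot[a, b] = m[10 - b, a]
  orient_lh <- matrix(0L, 9, 9); orient_lh[5, 5] <- 4L   # LH
  out_lh <- sharpen_true_edges(rot, mask, orient_lh, 4)
  expect_equal(out_lh[5, 5], out_lv[5, 5], tolerance = 1e-12)
})

test_that("project_edges is the corner-anchored lattice map", {
  e <- matrix(FALSE, 8, 8); o <- matrix(0L, 8, 8)
  e[4, 6] <- TRUE; o[4, 6] <- 3L   # 0-based (3, 5)
  p1 <- project_edges(e, o, 1L)
  expect_identical(p1$edges, e)
  expect_identical(p1$orientation, o)
  p2 <- project_edges(e, o, 2L)
  expect_identical(dim(p2$edges), c(16L, 16L))
  expect_identical(which(p2$edges), which(matrix(seq_len(256), 16) == 16 * 10 + 7))
  expect_identical(p2$orientation[7, 11], 3L)  # 0-based (6, 10)
  # count preservation on random masks
  for (seed in 1:5) {
    set.seed(seed)
    e <- matrix(runif(12 * 10) < 0.2, 12, 10)
    o <- matrix(sample(1:4, 120, TRUE), 12, 10) * e
    for (k in c(2L, 3L)) {
      pk <- project_edges(e, o, k)
      expect_identical(sum(pk$edges), sum(e))
      expect_identical(sort(pk$orientation[pk$edges]), sort(o[e]))
    }
  }
  expect_error(project_edges(e, matrix(0L, 3, 3), 2), "mismatch")
})

test_that("split_true_pseudo matches the brute-force Chebyshev oracle", {
  expect_identical(split_true_pseudo(matrix(TRUE, 4, 4), matrix(TRUE, 4, 4), 1),
                   matrix(FALSE, 4, 4))
  hr <- matrix(c(TRUE, rep(FALSE, 15)), 4, 4)
  expect_identical(split_true_pseudo(hr, matrix(FALSE, 4, 4), 3), hr)
  for (seed in 1:6) {
    set.seed(seed)
    hr <- matrix(runif(15 * 13) < 0.25, 15, 13)
    tr <- matrix(runif(15 * 13) < 0.08, 15, 13)
    for (tol in 0:2) {
      got <- split_true_pseudo(hr, tr, tol)
      expect_identical(got, oracle_pseudo_split(hr, tr, tol),
                       info = sprintf("seed %d tol %d", seed, tol))
      expect_false(any(got & tr))
    }
  }
})

test_that("soften_pseudo_edges equals the 8-neighbour-mean oracle", {
  m <- rand_image(7, 7, 31)
  mask <- matrix(FALSE, 7, 7)
  set.seed(32)
  mask[sample(49, 5)] <- TRUE
  out <- soften_pseudo_edges(m, mask)
  for (r in 1:7) for (c in 1:7) {
    expected <- if (mask[r, c]) oracle_neighbor_mean(m, r, c) else m[r, c]
    expect_equal(out[r, c], expected, tolerance = 1e-12)
  }
  # center-excluded: neighbours all v -> v regardless of own value
  m2 <- matrix(0.3, 5, 5); m2[3, 3] <- 0.9
  mk <- matrix(FALSE, 5, 5); mk[3, 3] <- TRUE
  expect_equal(soften_pseudo_edges(m2, mk)[3, 3], 0.3, tolerance = 1e-12)
  expect_identical(soften_pseudo_edges(m, matrix(FALSE, 7, 7)), m)
})

test_that("sharpen_true_edges equals the weighted-sum oracle", {
  # published example: center 0.8, along-edge neighbours 0.4, ratio 4 -> 0.6
  m <- matrix(0.8, 7, 7)
  m[4 - 1, 4 - 2] <- 0.4; m[4 + 1, 4 + 2] <- 0.4
  mask <- matrix(FALSE, 7, 7); mask[4, 4] <- TRUE
  orient <- matrix(0L, 7, 7); orient[4, 4] <- 2L  # LV
  expect_equal(sharpen_true_edges(m, mask, orient, 4)[4, 4], 0.6,
               tolerance = 1e-12)
  # random patches, all orientations, against the loop oracle
  for (seed in 1:4) {
    m <- rand_image(9, 9, 100 + seed)
    set.seed(seed)
    mask <- matrix(runif(81) < 0.3, 9, 9)
    orient <- matrix(0L, 9, 9)
    orient[mask] <- sample(1:4, sum(mask), TRUE)
    out <- sharpen_true_edges(m, mask, orient, 4)
    for (r in 1:9) for (c in 1:9) {
      expected <- if (mask[r, c]) {
        off <- tedi:::blend_offsets(ORIENTATION_LEVELS[orient[r, c] + 1L])
        oracle_sharpen_value(m, r, c, off, 4)
      } else m[r, c]
      expect_equal(out[r, c], expected, tolerance = 1e-12)
    }
  }
  # flat neighbourhood is invariant; unlabeled edge pixel errors
  flat <- matrix(0.4, 9, 9)
  expect_equal(sharpen_true_edges(flat, mask, orient, 4), flat,
               tolerance = 1e-12)
  expect_error(sharpen_true_edges(m, mask, matrix(0L, 9, 9), 4), "label")
})

test_that("constant input interpolates to the bilinear constant exactly", {
  flat <- gray_image(matrix(0.7, 16, 16))
  out <- tedi_interpolate(flat, tedi_config(factor = 2))
  expect_identical(dim(out), c(32L, 32L))
  expect_identical(out$pixels, resample(flat, 2, "bilinear")$pixels)
  expect_identical(attr(out, "n_true") + attr(out, "n_pseudo"), 0L)
})

test_that("TEDI differs from bilinear only on the true/pseudo sets", {
  for (kind in c("disk", "spine_band", "checker")) {
    lr <- make_phantom(phantom_spec(kind, c(48, 40), seed = 5))
    out <- tedi_interpolate(lr, tedi_config(factor = 2))
    base <- resample(lr, 2, "bilinear")
    touched <- attr(out, "true_edges") | attr(out, "pseudo_edges")
    expect_identical(out$pixels[!touched], base$pixels[!touched], info = kind)
    expect_gt(sum(touched), 0)
  }
})

test_that("TEDI is deterministic and respects range and degenerate sizes", {
  lr <- make_phantom(phantom_spec("ring", c(32, 32), noise_sigma = 0.05,
                                  seed = 3))
  a <- tedi_interpolate(lr, tedi_config())
  b <- tedi_interpolate(lr, tedi_config())
  expect_identical(a$pixels, b$pixels)
  expect_true(all(a$pixels >= 0 & a$pixels <= 1))
  # minimum-size input: 3x3 at factor 2 gives a 6x6 grid, large enough for
  # refinement; sub-minimum inputs are rejected outright
  tiny <- tedi_interpolate(gray_image(rand_image(3, 3, 1)), tedi_config())
  expect_identical(dim(tiny), c(6L, 6L))
  expect_error(tedi_interpolate(gray_image(matrix(0.5, 2, 2)), tedi_config()),
               "at least 3")
})

test_that("config defaults match the published operating point", {
  cfg <- tedi_config()
  expect_identical(cfg$factor, 2L)
  expect_equal(cfg$canny_threshold, 0.1)
  expect_equal(cfg$ratio, 4.0)
  expect_identical(cfg$true_edge_tolerance, 1L)
  expect_identical(cfg$base_method, "bilinear")
  expect_error(tedi_config(ratio = 0.5), ">= 1")
  expect_error(tedi_config(factor = 0), ">= 1")
})

test_that("calibrate_ratio composes SNR over the corpus deterministically", {
  corpus <- make_corpus(2, c(64, 64), seed = 19, noise_sigma = 0)
  tab <- calibrate_ratio(corpus[1], c(4, 4))
  expect_identical(tab$mean_snr_db[1], tab$mean_snr_db[2])  # duplicate rows
  ref <- tedi:::crop_multiple(corpus[[1]], 4L)
  direct <- snr(ref, tedi_interpolate(degrade(ref), tedi_config()))
  expect_equal(tab$mean_snr_db[1], direct, tolerance = 1e-12)
  expect_error(calibrate_ratio(list(), c(1, 4)), "non-empty")
  expect_error(calibrate_ratio(corpus, numeric(0)), "non-empty")
})
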