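# Image container, file I/O and classical resamplers.

test_that("gray_image validates its contract", {
  expect_error(gray_image(matrix(c(0, 2), 1, 2)), "\\[0, 1\\]")
  expect_error(gray_image(matrix(NA_real_, 2, 2)), "finite")
  expect_error(gray_image(matrix(0.5, 4, 4), source_depth = 12), "8 or 16")
  img <- gray_image(matrix(0.5, 4, 6), 16L)
  expect_identical(dim(img), c(4L, 6L))
  expect_identical(img$source_depth, 16L)
})

test_that("PNG round trip preserves pixels within one quantization step", {
  img <- gray_image(rand_image(15, 20, 101), 16L)
  f16 <- withr::local_tempfile(fileext = ".png")
  write_image(img, f16, depth = 16)
  back <- read_image(f16)
  expect_identical(back$source_depth, 16L)
  expect_lt(max(abs(back$pixels - img$pixels)), 1 / 65535 + 1e-12)
  f8 <- withr::local_tempfile(fileext = ".png")
  write_image(img, f8, depth = 8)
  back8 <- read_image(f8)
  expect_identical(back8$source_depth, 8L)
  expect_lte(max(abs(back8$pixels - img$pixels)), 0.5 / 255 + 1e-12)
})

test_that("TIFF round trip preserves pixels within one quantization step", {
  img <- gray_image(rand_image(13, 9, 202), 8L)
  for (depth in c(8L, 16L)) {
    f <- withr::local_tempfile(fileext = ".tif")
    write_image(img, f, depth = depth)
    back <- read_image(f)
    expect_identical(back$source_depth, depth)
    expect_lte(max(abs(back$pixels - img$pixels)), 0.5 / (2^depth - 1) + 1e-12)
  }
})

test_that("8-bit quantization stores round(v * 255)", {
  f <- withr::local_tempfile(fileext = ".png")
  write_image(gray_image(matrix(0.5, 8, 8)), f, depth = 8)
  back <- read_image(f)
  expect_equal(unique(as.vector(back$pixels)), 128 / 255, tolerance = 1e-12)
})

test_that("full-scale and zero images survive load exactly", {
  f <- withr::local_tempfile(fileext = ".png")
  write_image(gray_image(matrix(1, 8, 8)), f, depth = 8)
  expect_true(all(read_image(f)$pixels == 1))
  f2 <- withr::local_tempfile(fileext = ".tif")
  write_image(gray_image(matrix(0, 8, 8)), f2, depth = 16)
  expect_true(all(read_image(f2)$pixels == 0))
})

test_that("codecs agree with an independent implementation (Pillow)", {
  img <- gray_image(rand_image(12, 17, 303), 16L)
  f <- withr::local_tempfile(fileext = ".png")
  write_image(img, f, depth = 16)
  script <- paste(
    "from PIL import Image; import numpy as np, sys",
    sprintf("a = np.asarray(Image.open(%s))", shQuote(f, "cmd")),
    "print(a.dtype.name); print(a.shape[0], a.shape[1]); print(int(a.sum()))",
    sep = "; ")
  out <- system2("python", c("-c", shQuote(script)), stdout = TRUE)
  expect_identical(out[1], "uint16")
  expect_identical(out[2], "12 17")
  expect_identical(as.numeric(out[3]), sum(round(img$pixels * 65535)))
  # and read back a Pillow-written gray PNG
  f2 <- withr::local_tempfile(fileext = ".png")
  script2 <- paste(
    "from PIL import Image; import numpy as np",
    "a = (np.arange(200, dtype=np.uint8).reshape(10, 20) * 1)",
    sprintf("Image.fromarray(a, mode='L').save(%s)", shQuote(f2, "cmd")),
    sep = "; ")
  system2("python", c("-c", shQuote(script2)))
  back <- read_image(f2)
  expect_equal(back$pixels, matrix(0:199, 10, 20, byrow = TRUE) / 255,
               tolerance = 1e-12)
})

test_that("RGB input converts by BT.601 luminance", {
  rgb <- array(0, dim = c(3, 4, 3))
  set.seed(404)
  rgb[] <- runif(length(rgb))
  f <- withr::local_tempfile(fileext = ".png")
  png::writePNG(rgb, f)
  img <- read_image(f)
  q <- round(rgb * 255) / 255  # file quantization
  lum <- 0.299 * q[, , 1] + 0.587 * q[, , 2] + 0.114 * q[, , 3]
  expect_equal(img$pixels, lum, tolerance = 1e-12)
})

test_that("I/O error paths are reported", {
  expect_error(read_image("no/such/file.png"), "not found")
  expect_error(read_image(withr::local_tempfile(fileext = ".bmp")), "not found")
  f <- withr::local_tempfile(fileext = ".bmp")
  writeBin(as.raw(1:10), f)
  expect_error(read_image(f), "unsupported")
  expect_error(write_image(gray_image(matrix(0.5, 4, 4)), ""), "empty")
})

test_that("resample identity and flat invariance hold for every method", {
  img <- gray_image(rand_image(9, 11, 505))
  for (m in c("nearest", "bilinear", "bicubic")) {
    expect_equal(resample(img, 1, m)$pixels, img$pixels, tolerance = 1e-12,
                 info = m)
    flat <- resample(gray_image(matrix(0.7, 8, 8)), 2, m)
    expect_true(all(abs(flat$pixels - 0.7) < 1e-12), info = m)
    expect_identical(dim(flat), c(16L, 16L))
  }
  expect_error(resample(img, 0), "positive")
  expect_error(resample(img, -2), "positive")
})

test_that("bilinear x2 matches the closed-form corner-anchored formula", {
  img <- gray_image(matrix(c(0, 0, 1, 1), 2, 2))
  out <- resample(img, 2, "bilinear")$pixels
  # src col coords 0, 0.5, 1, 1.5(clamped): values 0, 0.5, 1, 1
  expect_equal(out, matrix(rep(c(0, 0.5, 1, 1), each = 4), 4, 4),
               tolerance = 1e-12)
  # general oracle on a random 2x2 at all 16 positions
  m <- rand_image(2, 2, 606)
  o2 <- resample(gray_image(m), 2, "bilinear")$pixels
  for (r in 0:3) for (c in 0:3) {
    sy <- min(r / 2, 1); sx <- min(c / 2, 1)
    fy <- sy - floor(sy); fx <- sx - floor(sx)
    r0 <- floor(sy) + 1; c0 <- floor(sx) + 1
    r1 <- min(r0 + 1, 2); c1 <- min(c0 + 1, 2)
    v <- (1 - fy) * ((1 - fx) * m[r0, c0] + fx * m[r0, c1]) +
      fy * ((1 - fx) * m[r1, c0] + fx * m[r1, c1])
    expect_equal(o2[r + 1, c + 1], v, tolerance = 1e-12)
  }
})

test_that("downscale/upscale factors reproduce the protocol sizes", {
  img <- gray_image(matrix(0.4, 360, 320))
  small <- resample(img, 0.5, "nearest")
  expect_identical(dim(small), c(180L, 160L))
  big <- resample(small, 4, "nearest")
  expect_identical(dim(big), c(720L, 640L))
})

test_that("nearest 0.5 downscale picks the block sample exactly", {
  set.seed(707)
  blocks <- matrix(runif(8 * 8), 8, 8)
  img <- blocks[rep(1:8, each = 2), rep(1:8, each = 2)]  # 2x2-constant
  down <- resample(gray_image(img), 0.5, "nearest")$pixels
  expect_equal(down, blocks, tolerance = 1e-15)
})
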