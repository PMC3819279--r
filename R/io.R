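# Image file I/O: PNG (read via the png package, written by a minimal
# grayscale encoder so 16-bit output is available) and baseline
# uncompressed grayscale TIFF (both directions implemented here; no TIFF
# package ships with the target environment).

# ITU-R BT.601 luminance weights for colour -> gray conversion
LUMA_WEIGHTS <- c(r = 0.299, g = 0.587, b = 0.114)

uint32_be <- function(x) {
  x <- as.numeric(x)
  as.raw(c(x %/% 16777216, x %/% 65536, x %/% 256, x) %% 256)
}

png_chunk <- function(type, data = raw(0)) {
  body <- c(charToRaw(type), data)
  c(uint32_be(length(data)), body, uint32_be(crc32_raw(body)))
}

# minimal PNG encoder: grayscale, non-interlaced, scanline filter 0
write_png_gray <- function(pixels, path, depth) {
  h <- nrow(pixels)
  w <- ncol(pixels)
  maxval <- 2^depth - 1
  q <- matrix(as.integer(round(pixels * maxval)), h, w)
  if (depth == 8L) {
    rows <- matrix(0L, nrow = w + 1L, ncol = h)
    rows[-1L, ] <- t(q)
  } else {
    rows <- matrix(0L, nrow = 2L * w + 1L, ncol = h)
    rows[seq(2L, 2L * w, by = 2L), ] <- t(q %/% 256L)  # big-endian samples
    rows[seq(3L, 2L * w + 1L, by = 2L), ] <- t(q %% 256L)
  }
  stream <- as.raw(as.vector(rows))
  ihdr <- c(uint32_be(w), uint32_be(h), as.raw(c(depth, 0L, 0L, 0L, 0L)))
  out <- c(as.raw(c(137, 80, 78, 71, 13, 10, 26, 10)),
           png_chunk("IHDR", ihdr),
           png_chunk("IDAT", memCompress(stream, type = "gzip")),
           png_chunk("IEND"))
  writeBin(out, path)
  invisible(path)
}

png_bit_depth <- function(path) {
  hdr <- readBin(path, "raw", n = 26L)
  if (length(hdr) < 26L) stop("not a PNG file: ", path)
  as.integer(hdr[25L])
}

read_png_gray <- function(path) {
  a <- png::readPNG(path)
  depth <- png_bit_depth(path)
  if (!depth %in% c(8L, 16L)) depth <- 8L  # 1/2/4-bit promoted on read
  if (length(dim(a)) == 3L) {
    nch <- dim(a)[3L]
    if (nch >= 3L) {
      m <- LUMA_WEIGHTS["r"] * a[, , 1L] + LUMA_WEIGHTS["g"] * a[, , 2L] +
        LUMA_WEIGHTS["b"] * a[, , 3L]
    } else {
      m <- a[, , 1L]  # gray + alpha: alpha dropped
    }
  } else {
    m <- a
  }
  gray_image(clip01(m), source_depth = depth)
}

# --- minimal baseline TIFF (little-endian, uncompressed, grayscale) ---

tiff_entry <- function(tag, type, count, value) {
  c(writeBin(as.integer(tag), raw(), size = 2, endian = "little"),
    writeBin(as.integer(type), raw(), size = 2, endian = "little"),
    writeBin(as.integer(count), raw(), size = 4, endian = "little"),
    if (type == 3L) {
      c(writeBin(as.integer(value), raw(), size = 2, endian = "little"),
        as.raw(c(0, 0)))
    } else {
      writeBin(as.integer(value), raw(), size = 4, endian = "little")
    })
}

write_tiff_gray <- function(pixels, path, depth) {
  h <- nrow(pixels)
  w <- ncol(pixels)
  maxval <- 2^depth - 1
  q <- as.integer(round(t(pixels) * maxval))  # row-major scanlines
  data <- if (depth == 8L) {
    as.raw(q)
  } else {
    writeBin(q, raw(), size = 2, endian = "little")
  }
  data_offset <- 8L
  ifd_offset <- data_offset + length(data)
  entries <- list(
    tiff_entry(256L, 3L, 1L, w),              # ImageWidth
    tiff_entry(257L, 3L, 1L, h),              # ImageLength
    tiff_entry(258L, 3L, 1L, depth),          # BitsPerSample
    tiff_entry(259L, 3L, 1L, 1L),             # Compression: none
    tiff_entry(262L, 3L, 1L, 1L),             # Photometric: BlackIsZero
    tiff_entry(273L, 4L, 1L, data_offset),    # StripOffsets
    tiff_entry(277L, 3L, 1L, 1L),             # SamplesPerPixel
    tiff_entry(278L, 3L, 1L, h),              # RowsPerStrip
    tiff_entry(279L, 4L, 1L, length(data))    # StripByteCounts
  )
  out <- c(charToRaw("II"),
           writeBin(42L, raw(), size = 2, endian = "little"),
           writeBin(as.integer(ifd_offset), raw(), size = 4, endian = "little"),
           data,
           writeBin(as.integer(length(entries)), raw(), size = 2, endian = "little"),
           do.call(c, entries),
           as.raw(c(0, 0, 0, 0)))
  writeBin(out, path)
  invisible(path)
}

read_uint <- function(raw, offset, size, endian) {
  b <- as.integer(raw[offset + seq_len(size)])
  if (endian == "little") b <- rev(b)
  Reduce(function(a, x) a * 256 + x, b, accumulate = FALSE)
}

read_tiff_gray <- function(path) {
  rawv <- readBin(path, "raw", n = file.info(path)$size)
  order_tag <- rawToChar(rawv[1:2])
  endian <- switch(order_tag, II = "little", MM = "big",
                   stop("not a TIFF file: ", path))
  if (read_uint(rawv, 2L, 2L, endian) != 42L) stop("not a TIFF file: ", path)
  ifd <- read_uint(rawv, 4L, 4L, endian)
  n_entries <- read_uint(rawv, ifd, 2L, endian)
  tags <- list()
  for (i in seq_len(n_entries)) {
    off <- ifd + 2L + (i - 1L) * 12L
    tag <- read_uint(rawv, off, 2L, endian)
    type <- read_uint(rawv, off + 2L, 2L, endian)
    count <- read_uint(rawv, off + 4L, 4L, endian)
    vsize <- switch(as.character(type), `1` = 1L, `3` = 2L, `4` = 4L, NA_integer_)
    values <- NA
    if (!is.na(vsize)) {
      voff <- if (vsize * count <= 4L) off + 8L else read_uint(rawv, off + 8L, 4L, endian)
      values <- vapply(seq_len(count) - 1L, function(k) {
        read_uint(rawv, voff + k * vsize, vsize, endian)
      }, numeric(1))
    }
    tags[[as.character(tag)]] <- values
  }
  need <- function(tag, default = NULL) {
    v <- tags[[as.character(tag)]]
    if (is.null(v)) {
      if (is.null(default)) stop("TIFF missing required tag ", tag)
      default
    } else v
  }
  w <- need(256L)
  h <- need(257L)
  depth <- need(258L, 8L)[1L]
  if (!depth %in% c(8, 16)) stop("unsupported TIFF bit depth: ", depth)
  if (need(259L, 1L) != 1) stop("only uncompressed TIFF is supported")
  spp <- need(277L, 1L)
  photometric <- need(262L, 1L)
  if (!photometric %in% c(0, 1, 2)) stop("unsupported TIFF photometric: ", photometric)
  offsets <- need(273L)
  counts <- need(279L, h * w * spp * depth / 8)
  bytes <- do.call(c, lapply(seq_along(offsets), function(k) {
    rawv[offsets[k] + seq_len(counts[k])]
  }))
  n <- h * w * spp
  vals <- if (depth == 8) {
    as.numeric(bytes) / 255
  } else {
    u <- readBin(bytes, "integer", n = n, size = 2, signed = FALSE, endian = endian)
    u / 65535
  }
  if (spp >= 3) {
    px <- matrix(vals, nrow = spp)
    vals <- LUMA_WEIGHTS["r"] * px[1L, ] + LUMA_WEIGHTS["g"] * px[2L, ] +
      LUMA_WEIGHTS["b"] * px[3L, ]
  }
  m <- matrix(vals, nrow = h, ncol = w, byrow = TRUE)
  if (photometric == 0) m <- 1 - m  # WhiteIsZero
  gray_image(clip01(m), source_depth = as.integer(depth))
}

file_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("png")) return("png")
  if (ext %in% c("tif", "tiff")) return("tiff")
  stop("unsupported image format '", ext, "' (expected PNG or TIFF): ", path)
}

#' Read a grayscale image
#'
#' Reads an 8- or 16-bit PNG or TIFF file into a [gray_image]. Colour inputs
#' are converted to luminance with ITU-R BT.601 weights
#' (0.299 R + 0.587 G + 0.114 B) before normalization to `[0, 1]`.
#'
#' @param path path to a `.png`, `.tif` or `.tiff` file.
#' @return A [gray_image] with `source_depth` matching the file.
#' @seealso [write_image()]
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- switch(file_format(path),
                png = read_png_gray(path),
                tiff = read_tiff_gray(path))
  if (img$height < 1 || img$width < 1) stop("zero-sized image: ", path)
  img
}

#' Write a grayscale image
#'
#' Writes a [gray_image] as grayscale PNG or TIFF at the requested bit depth.
#' A write/read round trip at the native depth changes no pixel by more than
#' one quantization step (`1/255` or `1/65535`).
#'
#' @param img a [gray_image] (or numeric matrix in `[0, 1]`).
#' @param path output path; format chosen from the extension.
#' @param depth output bit depth, 8 or 16; defaults to the image's
#'   `source_depth`.
#' @return The path, invisibly.
#' @export
write_image <- function(img, path, depth = NULL) {
  pixels <- as_pixels(img)
  if (is.null(depth)) {
    depth <- if (inherits(img, "gray_image")) img$source_depth else 8L
  }
  depth <- as.integer(depth)
  if (!depth %in% c(8L, 16L)) stop("depth must be 8 or 16")
  if (!nzchar(path)) stop("empty output path")
  fmt <- file_format(path)
  ok <- dir.exists(dirname(path))
  if (!ok) stop("output directory does not exist: ", dirname(path))
  switch(fmt,
         png = write_png_gray(pixels, path, depth),
         tiff = write_tiff_gray(pixels, path, depth))
  invisible(path)
}
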