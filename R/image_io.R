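#' @title Image grids
#' @description
#' Throughout the package an image ("ImageGrid") is a plain numeric matrix
#' indexed `img[row, col]` with R's native 1-based indices, row 1 at the top.
#' Intensities are expected in `[0, 1]` after [normalize_unit()]; readers
#' return raw (unnormalized) sample values with a `bit_depth` attribute.
#' @name image-grid
NULL

#' Read a 2D grayscale image (PNG, TIFF or NIfTI slice)
#'
#' Decodes a file into a numeric matrix of raw intensities. PNG decoding is
#' delegated to the \pkg{png} package; uncompressed grayscale TIFF (8/16-bit)
#' and NIfTI-1 (`.nii`) are decoded by small built-in codecs since no R codec
#' for them is otherwise available. Intensities are *not* normalized; see
#' [normalize_unit()].
#'
#' @param path file path.
#' @param format `"auto"` (from extension), `"png"`, `"tiff"` or `"nifti"`.
#' @param slice_axis,slice_index for 3D NIfTI volumes, the axis (1-3) and
#'   1-based index of the 2D slice to extract. Required for 3D input.
#' @param channel for multi-channel PNG input, the channel to extract
#'   (an error demands an explicit choice otherwise).
#' @return numeric matrix with attributes `bit_depth` and `source`.
#' @export
load_image <- function(path, format = c("auto", "png", "tiff", "nifti"),
                       slice_axis = NULL, slice_index = NULL, channel = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_mcnedi("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
    format <- switch(ext,
      png = "png", tif = "tiff", tiff = "tiff", nii = "nifti",
      stop_mcnedi("cannot infer format from extension '", ext,
                  "'; pass format= explicitly"))
  }
  img <- switch(format,
    png   = read_png_gray(path, channel = channel),
    tiff  = read_tiff_gray(path),
    nifti = read_nifti_image(path, slice_axis, slice_index))
  attr(img, "source") <- path
  img
}

#' Write a 2D grayscale image
#'
#' Quantizes intensities in `[0, 1]` to the requested bit depth and writes
#' PNG (8-bit, via \pkg{png}), uncompressed grayscale TIFF (8/16-bit) or a
#' 2D float32 NIfTI-1 file (no quantization).
#'
#' @param image numeric matrix with values in `[0, 1]`.
#' @param path output file path.
#' @param format `"auto"` (from extension), `"png"`, `"tiff"` or `"nifti"`.
#' @param bit_depth 8 or 16 (TIFF only; PNG writes 8-bit, NIfTI float32).
#' @return `path`, invisibly.
#' @export
save_image <- function(image, path, format = c("auto", "png", "tiff", "nifti"),
                       bit_depth = 16L) {
  assert_image(image)
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      png = "png", tif = "tiff", tiff = "tiff", nii = "nifti",
      stop_mcnedi("cannot infer format from extension '", ext, "'"))
  }
  if (min(image) < -1e-9 || max(image) > 1 + 1e-9)
    stop_mcnedi("save_image expects intensities in [0, 1]; normalize first")
  image <- clip01(image)
  switch(format,
    png = png::writePNG(image, target = path),
    tiff = {
      if (!bit_depth %in% c(8L, 16L)) stop_mcnedi("bit_depth must be 8 or 16")
      write_tiff_gray(round(image * (2^bit_depth - 1)), path, bit_depth)
    },
    nifti = write_nifti_image(image, path))
  invisible(path)
}

read_png_gray <- function(path, channel = NULL) {
  x <- tryCatch(png::readPNG(path, info = TRUE),
                error = function(e) stop_mcnedi("failed to decode PNG '", path,
                                                "': ", conditionMessage(e)))
  info <- attr(x, "info")
  depth <- if (!is.null(info$bit.depth)) info$bit.depth else 8L
  if (length(dim(x)) == 3L) {
    if (is.null(channel))
      stop_mcnedi("multi-channel PNG (", dim(x)[3], " channels): pass ",
                  "channel= to select one explicitly")
    if (channel < 1 || channel > dim(x)[3])
      stop_mcnedi("channel out of range")
    x <- x[, , channel]
  }
  out <- round(x * (2^depth - 1))
  attr(out, "bit_depth") <- as.integer(depth)
  out
}

# ---- minimal uncompressed grayscale TIFF codec ------------------------------
# Baseline TIFF, single sample per pixel, no compression, 8 or 16 bits.
# Sufficient for the package's own fixtures; anything fancier errors clearly.

write_tiff_gray <- function(ints, path, bits) {
  stopifnot(is.matrix(ints))
  maxv <- 2^bits - 1
  if (min(ints) < 0 || max(ints) > maxv)
    stop_mcnedi("pixel values exceed ", bits, "-bit range")
  h <- nrow(ints); w <- ncol(ints)
  con <- file(path, "wb"); on.exit(close(con))
  data_bytes <- h * w * (bits %/% 8L)
  ifd_offset <- 8L + data_bytes
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(as.integer(ifd_offset), con, size = 4, endian = "little")
  # pixel data, row-major
  v <- as.integer(t(ints))
  if (bits == 8L) writeBin(as.raw(v), con)
  else {
    # writeBin size=2 is signed; map to [-32768, 32767]
    writeBin(as.integer(ifelse(v > 32767L, v - 65536L, v)), con,
             size = 2, endian = "little")
  }
  entry <- function(tag, type, count, value) {
    writeBin(as.integer(tag), con, size = 2, endian = "little")
    writeBin(as.integer(type), con, size = 2, endian = "little")
    writeBin(as.integer(count), con, size = 4, endian = "little")
    if (type == 3L) {  # SHORT padded to 4 bytes
      writeBin(as.integer(value), con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else writeBin(as.integer(value), con, size = 4, endian = "little")
  }
  entries <- list(
    c(256L, 4L, 1L, w),            # ImageWidth
    c(257L, 4L, 1L, h),            # ImageLength
    c(258L, 3L, 1L, bits),         # BitsPerSample
    c(259L, 3L, 1L, 1L),           # Compression: none
    c(262L, 3L, 1L, 1L),           # Photometric: BlackIsZero
    c(273L, 4L, 1L, 8L),           # StripOffsets
    c(277L, 3L, 1L, 1L),           # SamplesPerPixel
    c(278L, 4L, 1L, h),            # RowsPerStrip
    c(279L, 4L, 1L, data_bytes))   # StripByteCounts
  writeBin(length(entries), con, size = 2, endian = "little")
  for (e in entries) entry(e[1], e[2], e[3], e[4])
  writeBin(0L, con, size = 4, endian = "little")  # no next IFD
  invisible(path)
}

read_tiff_gray <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 8) stop_mcnedi("truncated TIFF '", path, "'")
  endian <- if (rawToChar(raw[1:2]) == "II") "little"
            else if (rawToChar(raw[1:2]) == "MM") "big"
            else stop_mcnedi("not a TIFF file: '", path, "'")
  rd <- function(off, size, n = 1L, signed = TRUE) {
    if (off + size * n - 1L > length(raw))
      stop_mcnedi("truncated TIFF '", path, "'")
    readBin(raw[off:(off + size * n - 1L)], "integer", n = n, size = size,
            endian = endian, signed = signed)
  }
  if (rd(3L, 2L, signed = FALSE) != 42L) stop_mcnedi("bad TIFF magic")
  ifd <- rd(5L, 4L) + 1L  # to 1-based raw offset
  n_entries <- rd(ifd, 2L, signed = FALSE)
  tags <- list()
  for (k in seq_len(n_entries)) {
    base <- ifd + 2L + (k - 1L) * 12L
    tag <- rd(base, 2L, signed = FALSE)
    type <- rd(base + 2L, 2L, signed = FALSE)
    count <- rd(base + 4L, 4L)
    val <- if (type == 3L) rd(base + 8L, 2L, n = min(count, 2L), signed = FALSE)
           else rd(base + 8L, 4L)
    if (type == 3L && count > 2L) val <- rd(val[1] + 1L, 2L, n = count, signed = FALSE)
    if (type == 4L && count > 1L) val <- rd(val + 1L, 4L, n = count)
    tags[[as.character(tag)]] <- val
  }
  need <- function(tag, default = NULL) {
    v <- tags[[as.character(tag)]]
    if (is.null(v)) {
      if (is.null(default)) stop_mcnedi("TIFF missing required tag ", tag)
      v <- default
    }
    v
  }
  w <- need(256L); h <- need(257L)
  bits <- need(258L, 8L)[1]
  if (need(259L, 1L) != 1L) stop_mcnedi("compressed TIFF not supported")
  if (need(277L, 1L) != 1L) stop_mcnedi("multi-sample TIFF not supported")
  if (!bits %in% c(8L, 16L)) stop_mcnedi("only 8/16-bit TIFF supported")
  offsets <- need(273L); counts <- need(279L, h * w * bits %/% 8L)
  px <- integer(0)
  for (s in seq_along(offsets)) {
    o <- offsets[s] + 1L; nb <- counts[min(s, length(counts))]
    if (o + nb - 1L > length(raw)) stop_mcnedi("truncated TIFF '", path, "'")
    if (bits == 8L) px <- c(px, as.integer(raw[o:(o + nb - 1L)]))
    else {
      v <- readBin(raw[o:(o + nb - 1L)], "integer", n = nb %/% 2L, size = 2,
                   endian = endian, signed = FALSE)
      px <- c(px, v)
    }
  }
  if (length(px) < h * w) stop_mcnedi("truncated TIFF pixel data '", path, "'")
  out <- matrix(as.numeric(px[seq_len(h * w)]), nrow = h, ncol = w, byrow = TRUE)
  attr(out, "bit_depth") <- as.integer(bits)
  out
}

# ---- minimal NIfTI-1 codec --------------------------------------------------

read_nifti_image <- function(path, slice_axis = NULL, slice_index = NULL) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 348L) stop_mcnedi("truncated NIfTI '", path, "'")
  endian <- "little"
  hdr_size <- readBin(raw[1:4], "integer", size = 4, endian = endian)
  if (hdr_size != 348L) {
    endian <- "big"
    hdr_size <- readBin(raw[1:4], "integer", size = 4, endian = endian)
    if (hdr_size != 348L) stop_mcnedi("not a NIfTI-1 file: '", path, "'")
  }
  magic <- rawToChar(raw[345:347])
  if (!magic %in% c("n+1", "ni1")) stop_mcnedi("bad NIfTI magic in '", path, "'")
  dim0 <- readBin(raw[41:56], "integer", n = 8, size = 2, endian = endian)
  datatype <- readBin(raw[71:72], "integer", n = 1, size = 2, endian = endian)
  vox_offset <- readBin(raw[109:112], "numeric", n = 1, size = 4, endian = endian)
  scl_slope <- readBin(raw[113:116], "numeric", n = 1, size = 4, endian = endian)
  scl_inter <- readBin(raw[117:120], "numeric", n = 1, size = 4, endian = endian)
  nd <- dim0[1]
  if (nd < 2L) stop_mcnedi("NIfTI with fewer than 2 dimensions")
  dims <- dim0[2:(1 + nd)]
  n <- prod(dims)
  spec <- switch(as.character(datatype),
    "2" = list(what = "integer", size = 1, signed = FALSE, bits = 8L),
    "4" = list(what = "integer", size = 2, signed = TRUE, bits = 16L),
    "8" = list(what = "integer", size = 4, signed = TRUE, bits = 32L),
    "16" = list(what = "numeric", size = 4, signed = TRUE, bits = 32L),
    "64" = list(what = "numeric", size = 8, signed = TRUE, bits = 64L),
    "512" = list(what = "integer", size = 2, signed = FALSE, bits = 16L),
    stop_mcnedi("unsupported NIfTI datatype ", datatype))
  o <- as.integer(vox_offset) + 1L
  nb <- n * spec$size
  if (o + nb - 1L > length(raw)) stop_mcnedi("truncated NIfTI data in '", path, "'")
  v <- readBin(raw[o:(o + nb - 1L)], spec$what, n = n, size = spec$size,
               endian = endian, signed = spec$signed)
  if (!is.na(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    v <- v * scl_slope + scl_inter
  arr <- array(as.numeric(v), dim = dims)
  # collapse trailing singleton dimensions
  while (length(dim(arr)) > 2L && utils::tail(dim(arr), 1L) == 1L)
    arr <- array(arr, dim = utils::head(dim(arr), -1L))
  if (length(dim(arr)) > 2L) {
    if (is.null(slice_axis) || is.null(slice_index))
      stop_mcnedi("3D NIfTI volume: pass slice_axis and slice_index")
    nd2 <- length(dim(arr))
    if (slice_axis < 1L || slice_axis > nd2) stop_mcnedi("slice_axis out of range")
    if (slice_index < 1L || slice_index > dim(arr)[slice_axis])
      stop_mcnedi("slice_index out of range")
    idx <- rep(list(quote(expr = )), nd2)
    idx[[slice_axis]] <- slice_index
    arr <- do.call(`[`, c(list(arr), idx, list(drop = TRUE)))
  }
  out <- as.matrix(arr)
  attr(out, "bit_depth") <- spec$bits
  out
}

write_nifti_image <- function(image, path) {
  stopifnot(is.matrix(image))
  # Assemble the 348-byte header (+4 padding) in a raw vector for exact offsets.
  hdr <- raw(352)
  put_i <- function(off, x, size) {
    b <- writeBin(as.integer(x), raw(), size = size, endian = "little")
    hdr[(off + 1L):(off + length(b))] <<- b
  }
  put_f <- function(off, x) {
    b <- writeBin(as.numeric(x), raw(), size = 4, endian = "little")
    hdr[(off + 1L):(off + length(b))] <<- b
  }
  put_i(0L, 348L, 4)
  put_i(40L, c(2L, nrow(image), ncol(image), 1L, 1L, 1L, 1L, 1L), 2)
  put_i(70L, 16L, 2)                  # datatype: float32
  put_i(72L, 32L, 2)                  # bitpix
  put_f(76L, c(1, 1, 1, 1, 1, 1, 1, 1))  # pixdim
  put_f(108L, 352)                    # vox_offset
  put_f(112L, 1); put_f(116L, 0)      # scl_slope, scl_inter
  hdr[345:348] <- c(charToRaw("n+1"), as.raw(0L))
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(hdr, con)
  writeBin(as.numeric(image), con, size = 4, endian = "little")
  invisible(path)
}

# ---- intensity and geometry utilities ---------------------------------------

#' Min-max normalize intensities to the unit interval
#'
#' Affine map of the intensity range onto `[0, 1]`. A constant image maps to
#' all zeros (documented convention; avoids division by zero).
#'
#' @param image numeric matrix with finite values.
#' @return numeric matrix with `min 0`, `max 1` (or all zeros if constant).
#' @export
normalize_unit <- function(image) {
  assert_image(image)
  lo <- min(image); hi <- max(image)
  out <- if (hi > lo) (image - lo) / (hi - lo) else array(0, dim(image))
  out <- matrix(out, nrow(image), ncol(image))
  attr(out, "bit_depth") <- attr(image, "bit_depth")
  out
}

#' Integer translation with edge replication
#'
#' Shifts an image by a whole number of pixels along one of four directions
#' used in misregistration experiments: `slant` = (+k, +k), `anti-slant` =
#' (+k, -k), `vertical` = (+k, 0), `horizontal` = (0, +k), in (row, col)
#' displacement. Vacated borders are filled by edge replication so no
#' artificial zero-edges are injected into weight statistics.
#'
#' @param image numeric matrix.
#' @param direction one of `"slant"`, `"anti-slant"`, `"vertical"`,
#'   `"horizontal"`.
#' @param pixels nonnegative integer shift magnitude,
#'   `< min(dim(image)) / 2`.
#' @return shifted matrix, same shape.
#' @export
shift_image <- function(image, direction, pixels) {
  assert_image(image)
  if (!is.numeric(pixels) || length(pixels) != 1L || pixels < 0 ||
      pixels != round(pixels))
    stop_mcnedi("pixels must be a nonnegative integer")
  if (pixels >= min(dim(image)) / 2)
    stop_mcnedi("shift too large for image size")
  d <- switch(direction,
    "slant" = c(1L, 1L), "anti-slant" = c(1L, -1L),
    "vertical" = c(1L, 0L), "horizontal" = c(0L, 1L),
    stop_mcnedi("unknown direction '", direction, "'"))
  k <- as.integer(pixels)
  h <- nrow(image); w <- ncol(image)
  image[clamp_idx(seq_len(h) - d[1] * k, h),
        clamp_idx(seq_len(w) - d[2] * k, w), drop = FALSE]
}
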