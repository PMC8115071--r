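# Minimal TIFF codec for multichannel IMC planes.
#
# No TIFF library ships with this R installation, so the package carries a
# small reader/writer restricted to what IMC exports need: little-endian,
# one grayscale page (IFD) per channel, uncompressed, a single strip per
# page, 32-bit float samples (the writer) and uint8/16/32 or float32/64
# samples (the reader). Images are stored row-major in the file and exposed
# as `[channel, row, col]` arrays in R.

TIFF_TAGS <- c(width = 256L, height = 257L, bits = 258L, compression = 259L,
               photometric = 262L, strip_offsets = 273L, spp = 277L,
               rows_per_strip = 278L, strip_counts = 279L, sample_format = 339L)

#' Write a multichannel image as a multi-page float TIFF
#'
#' One grayscale page per channel, 32-bit IEEE float, uncompressed,
#' little-endian. Pixel values round-trip bit-exactly through
#' [read_imc_tiff()] (up to float32 precision of the input).
#'
#' @param pixels numeric array `[channel, row, col]` of non-negative
#'   intensities (a matrix is treated as one channel).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_imc_tiff <- function(pixels, path) {
  if (is.matrix(pixels)) pixels <- array(pixels, c(1L, dim(pixels)))
  stopifnot(length(dim(pixels)) == 3L)
  nc <- dim(pixels)[1]; h <- dim(pixels)[2]; w <- dim(pixels)[3]
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(0L, con, size = 4, endian = "little")  # first-IFD offset, patched below
  # layout: header(8) | per channel: strip data then IFD
  entry <- function(tag, type, value) c(tag = tag, type = type, value = value)
  n_entries <- 10L
  ifd_size <- 2L + n_entries * 12L + 4L
  offset <- 8L
  strip_bytes <- w * h * 4L
  for (ch in seq_len(nc)) {
    strip_off <- offset
    ifd_off <- strip_off + strip_bytes
    # strip is row-major: transpose the [row, col] plane before flattening
    writeBin(as.numeric(t(matrix(pixels[ch, , ], h, w))),
             con, size = 4, endian = "little")
    entries <- list(
      entry(TIFF_TAGS[["width"]], 4L, w),
      entry(TIFF_TAGS[["height"]], 4L, h),
      entry(TIFF_TAGS[["bits"]], 3L, 32L),
      entry(TIFF_TAGS[["compression"]], 3L, 1L),
      entry(TIFF_TAGS[["photometric"]], 3L, 1L),
      entry(TIFF_TAGS[["strip_offsets"]], 4L, strip_off),
      entry(TIFF_TAGS[["spp"]], 3L, 1L),
      entry(TIFF_TAGS[["rows_per_strip"]], 4L, h),
      entry(TIFF_TAGS[["strip_counts"]], 4L, strip_bytes),
      entry(TIFF_TAGS[["sample_format"]], 3L, 3L)
    )
    writeBin(as.integer(n_entries), con, size = 2, endian = "little")
    for (e in entries) {
      writeBin(as.integer(e[["tag"]]), con, size = 2, endian = "little")
      writeBin(as.integer(e[["type"]]), con, size = 2, endian = "little")
      writeBin(1L, con, size = 4, endian = "little")
      if (e[["type"]] == 3L) {  # SHORT: value left-justified in 4 bytes
        writeBin(as.integer(e[["value"]]), con, size = 2, endian = "little")
        writeBin(0L, con, size = 2, endian = "little")
      } else {
        writeBin(as.integer(e[["value"]]), con, size = 4, endian = "little")
      }
    }
    # the next channel's IFD sits after that channel's strip data
    next_ifd_off <- if (ch < nc) (ifd_off + ifd_size) + strip_bytes else 0L
    writeBin(as.integer(next_ifd_off), con, size = 4, endian = "little")
    offset <- ifd_off + ifd_size
  }
  # patch first IFD offset in header
  seek(con, 4L, rw = "write")
  writeBin(8L + strip_bytes, con, size = 4, endian = "little")
  invisible(path)
}

read_uint <- function(raw_vec, pos, n_bytes) {
  v <- 0
  for (i in rev(seq_len(n_bytes))) v <- v * 256 + as.integer(raw_vec[pos + i - 1L])
  v
}

#' Read a multi-page grayscale TIFF into a channel array
#'
#' Supports uncompressed little-endian grayscale pages with uint8/16/32 or
#' float32/64 samples; each page becomes one channel.
#'
#' @param path TIFF file path.
#' @return numeric array `[channel, row, col]`.
#' @export
read_imc_tiff <- function(path) {
  raw_vec <- readBin(path, "raw", n = file.info(path)$size)
  if (rawToChar(raw_vec[1:2]) != "II" || read_uint(raw_vec, 3L, 2L) != 42L)
    data_error("not a little-endian TIFF file")
  ifd_off <- read_uint(raw_vec, 5L, 4L)
  planes <- list()
  while (ifd_off != 0L) {
    n <- read_uint(raw_vec, ifd_off + 1L, 2L)
    tags <- list()
    for (i in seq_len(n)) {
      base <- ifd_off + 2L + (i - 1L) * 12L + 1L
      tag <- read_uint(raw_vec, base, 2L)
      type <- read_uint(raw_vec, base + 2L, 2L)
      count <- read_uint(raw_vec, base + 4L, 4L)
      size <- c(`1` = 1L, `3` = 2L, `4` = 4L)[as.character(type)]
      if (is.na(size)) { tags[[as.character(tag)]] <- NA; next }
      vals <- if (count * size <= 4L) {
        vapply(seq_len(count),
               function(k) read_uint(raw_vec, base + 8L + (k - 1L) * size, size), 0)
      } else {
        off <- read_uint(raw_vec, base + 8L, 4L)
        vapply(seq_len(count),
               function(k) read_uint(raw_vec, off + 1L + (k - 1L) * size, size), 0)
      }
      tags[[as.character(tag)]] <- vals
    }
    g <- function(id, default = NULL) tags[[as.character(id)]] %||% default
    w <- g(256L); h <- g(257L)
    bits <- g(258L, 1L)[1]; comp <- g(259L, 1L)
    fmt <- g(339L, 1L)[1]
    if (comp != 1L) data_error("compressed TIFF not supported")
    offs <- g(273L); cnts <- g(279L, w * h * bits / 8)
    buf <- raw(0)
    for (k in seq_along(offs))
      buf <- c(buf, raw_vec[(offs[k] + 1L):(offs[k] + cnts[k])])
    npx <- w * h
    vals <- if (fmt == 3L) {
      readBin(buf, "double", n = npx, size = bits / 8, endian = "little")
    } else {
      readBin(buf, "integer", n = npx, size = bits / 8, endian = "little",
              signed = bits < 32)
    }
    planes[[length(planes) + 1L]] <- matrix(vals, nrow = h, ncol = w, byrow = TRUE)
    ifd_off <- read_uint(raw_vec, ifd_off + 2L + n * 12L + 1L, 4L)
  }
  h <- nrow(planes[[1L]]); w <- ncol(planes[[1L]])
  out <- array(0, c(length(planes), h, w))
  for (ch in seq_along(planes)) out[ch, , ] <- planes[[ch]]
  out
}
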