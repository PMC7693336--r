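# Minimal baseline TIFF codec: little-endian, uncompressed, single-channel
# greyscale, 32-bit float samples, multi-page. Calibration metadata travels
# in the ImageDescription tag of the first page as a JSON string. This
# covers exactly the movies/stacks the package produces and consumes; RGB,
# compressed or tiled TIFFs are rejected with a clear error.

TIFF_TYPE_SIZES <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L, `5` = 8L,
                     `6` = 1L, `7` = 1L, `8` = 2L, `9` = 4L, `10` = 8L,
                     `11` = 4L, `12` = 8L)

#' Write a multi-page greyscale float TIFF
#'
#' @param path output file path.
#' @param data numeric array `[rows, cols, pages]` (a matrix is treated as
#'   one page).
#' @param description character scalar stored in the ImageDescription tag of
#'   every page (typically JSON metadata).
#' @return `path`, invisibly.
#' @export
write_tiff <- function(path, data, description = "") {
  if (is.matrix(data)) data <- array(data, c(dim(data), 1L))
  stopifnot(is.array(data), length(dim(data)) == 3)
  ny <- dim(data)[1]; nx <- dim(data)[2]; np <- dim(data)[3]
  con <- file(path, "wb")
  on.exit(close(con))
  wr2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  wr4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  writeChar("II", con, nchars = 2, eos = NULL)
  wr2(42L)
  desc_raw <- c(charToRaw(enc2utf8(description)), as.raw(0L))
  if (length(desc_raw) %% 2 == 1) desc_raw <- c(desc_raw, as.raw(0L))
  strip_bytes <- ny * nx * 4L
  n_entries <- 11L
  ifd_size <- 2L + 12L * n_entries + 4L
  # layout per page: [strip data][description][IFD]
  page_sizes <- strip_bytes + length(desc_raw) + ifd_size
  page_off <- 8L + (seq_len(np) - 1L) * page_sizes
  wr4(page_off[1] + strip_bytes + length(desc_raw))  # offset of first IFD
  for (p in seq_len(np)) {
    # pixel data, row-major within the strip
    writeBin(as.double(t(data[, , p])), con, size = 4, endian = "little")
    desc_off <- page_off[p] + strip_bytes
    writeBin(desc_raw, con)
    entry <- function(tag, type, count, value) {
      wr2(tag); wr2(type); wr4(count)
      if (type == 3L && count == 1L) { wr2(value); wr2(0L) } else wr4(value)
    }
    wr2(n_entries)
    entry(256L, 3L, 1L, nx)                      # ImageWidth
    entry(257L, 3L, 1L, ny)                      # ImageLength
    entry(258L, 3L, 1L, 32L)                     # BitsPerSample
    entry(259L, 3L, 1L, 1L)                      # Compression: none
    entry(262L, 3L, 1L, 1L)                      # Photometric: BlackIsZero
    entry(270L, 2L, length(desc_raw), desc_off)  # ImageDescription
    entry(273L, 4L, 1L, page_off[p])             # StripOffsets
    entry(277L, 3L, 1L, 1L)                      # SamplesPerPixel
    entry(278L, 3L, 1L, ny)                      # RowsPerStrip
    entry(279L, 4L, 1L, strip_bytes)             # StripByteCounts
    entry(339L, 3L, 1L, 3L)                      # SampleFormat: IEEE float
    wr4(if (p < np) page_off[p + 1L] + strip_bytes + length(desc_raw) else 0L)
  }
  invisible(path)
}

#' Read a greyscale multi-page TIFF
#'
#' Supports uncompressed single-channel pages with 8/16-bit unsigned or
#' 32-bit float samples (the subset this package writes, plus common
#' ImageJ-style greyscale exports).
#'
#' @param path TIFF file path.
#' @return list with `data` (array `[rows, cols, pages]`) and `description`
#'   (ImageDescription string of the first page, or `""`).
#' @export
read_tiff <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 8) stopf("not a TIFF file: %s", path)
  order <- rawToChar(raw[1:2])
  endian <- if (order == "II") "little" else if (order == "MM") "big" else
    stopf("not a TIFF file: %s", path)
  u16 <- function(off) readBin(raw[(off + 1):(off + 2)], "integer",
                               size = 2, signed = FALSE, endian = endian)
  u32 <- function(off) readBin(raw[(off + 1):(off + 4)], "integer",
                               size = 4, endian = endian)
  if (u16(2) != 42L) stopf("not a TIFF file: %s", path)
  read_values <- function(type, count, off_field) {
    size <- TIFF_TYPE_SIZES[[as.character(type)]] * count
    off <- if (size <= 4) off_field else u32(off_field)
    bytes <- raw[(off + 1):(off + size)]
    switch(as.character(type),
      `2` = rawToChar(bytes[bytes != as.raw(0)]),
      `3` = readBin(bytes, "integer", n = count, size = 2, signed = FALSE,
                    endian = endian),
      `4` = readBin(bytes, "integer", n = count, size = 4, endian = endian),
      `1` = as.integer(bytes),
      stopf("unsupported TIFF tag type %d", type))
  }
  pages <- list(); description <- ""
  ifd_off <- u32(4)
  while (ifd_off != 0) {
    n <- u16(ifd_off)
    tags <- list()
    for (i in seq_len(n)) {
      e <- ifd_off + 2 + (i - 1) * 12
      tags[[as.character(u16(e))]] <-
        list(type = u16(e + 2), count = u32(e + 4), off = e + 8)
    }
    g <- function(tag, default = NULL) {
      t <- tags[[as.character(tag)]]
      if (is.null(t)) return(default)
      read_values(t$type, t$count, t$off)
    }
    nx <- g(256); ny <- g(257)
    if (is.null(nx) || is.null(ny)) stopf("malformed TIFF: missing dimensions")
    if (!identical(g(259, 1L), 1L)) stopf("unsupported TIFF: compressed data")
    spp <- g(277, 1L)
    if (spp != 1L) stopf("unsupported TIFF format: %d samples/pixel (RGB?)", spp)
    bits <- g(258, 1L)
    fmt <- g(339, 1L)
    offs <- g(273); counts <- g(279)
    if (is.null(offs)) stopf("malformed TIFF: missing strip offsets")
    if (is.null(counts)) counts <- rep(ny * nx * bits %/% 8 / length(offs),
                                       length(offs))
    bytes <- unlist(lapply(seq_along(offs), function(i)
      raw[(offs[i] + 1):(offs[i] + counts[i])]))
    vals <- if (fmt == 3L && bits == 32L)
      readBin(bytes, "double", n = ny * nx, size = 4, endian = endian)
    else if (fmt %in% c(1L, NA) && bits == 8L)
      as.double(as.integer(bytes))
    else if (fmt == 1L && bits == 16L)
      as.double(readBin(bytes, "integer", n = ny * nx, size = 2,
                        signed = FALSE, endian = endian))
    else stopf("unsupported TIFF sample format (bits=%s, format=%s)",
               bits, fmt)
    pages[[length(pages) + 1L]] <- t(matrix(vals, nrow = nx, ncol = ny))
    if (description == "") description <- g(270, "")
    ifd_off <- u32(ifd_off + 2 + n * 12)
  }
  if (!length(pages)) stopf("TIFF contains no pages: %s", path)
  d <- dim(pages[[1]])
  data <- array(unlist(pages), c(d[1], d[2], length(pages)))
  list(data = data, description = description)
}
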