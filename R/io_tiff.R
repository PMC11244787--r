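# Minimal TIFF codec: uncompressed baseline grayscale (8/16-bit) and RGB
# (read as Rec.601 luminance). Written files are little-endian, 8-bit,
# single strip. No compression codecs are supported by design.

u16_le <- function(x) as.raw(c(x %% 256, x %/% 256))
u32_le <- function(x) as.raw(c(x %% 256, (x %/% 256) %% 256,
                               (x %/% 65536) %% 256, x %/% 16777216))

tiff_write_gray <- function(img, path) {
  m <- nrow(img); n <- ncol(img)
  entry <- function(tag, type, count, value) {
    # type 3 = SHORT (pad to 4 bytes), 4 = LONG
    val <- if (type == 3L) c(u16_le(value), as.raw(c(0, 0))) else u32_le(value)
    c(u16_le(tag), u16_le(type), u32_le(count), val)
  }
  n_entries <- 9L
  data_off <- 8L + 2L + 12L * n_entries + 4L
  ifd <- c(
    u16_le(n_entries),
    entry(256L, 4L, 1L, n),          # ImageWidth
    entry(257L, 4L, 1L, m),          # ImageLength
    entry(258L, 3L, 1L, 8L),         # BitsPerSample
    entry(259L, 3L, 1L, 1L),         # Compression: none
    entry(262L, 3L, 1L, 1L),         # Photometric: BlackIsZero
    entry(273L, 4L, 1L, data_off),   # StripOffsets
    entry(277L, 3L, 1L, 1L),         # SamplesPerPixel
    entry(278L, 4L, 1L, m),          # RowsPerStrip
    entry(279L, 4L, 1L, m * n),      # StripByteCounts
    u32_le(0L)
  )
  out <- c(charToRaw("II"), u16_le(42L), u32_le(8L), ifd, as.raw(t(img)))
  ok <- tryCatch({ writeBin(out, path); TRUE }, error = function(e) FALSE,
                 warning = function(w) FALSE)
  if (!ok) stop_io("cannot write TIFF file '%s'", path)
  invisible(path)
}

tiff_read <- function(path) {
  size <- file.info(path)$size
  bytes <- readBin(path, "raw", n = size)
  if (length(bytes) < 8L) stop_io("truncated TIFF file '%s'", path)
  order_tag <- rawToChar(bytes[1:2])
  le <- if (order_tag == "II") TRUE else if (order_tag == "MM") FALSE
        else stop_io("'%s' is not a TIFF file", path)
  rd <- function(r) {  # raw -> integer with declared endianness
    v <- as.numeric(r)
    if (le) sum(v * 256^(seq_along(v) - 1)) else sum(v * 256^(rev(seq_along(v)) - 1))
  }
  if (rd(bytes[3:4]) != 42) stop_io("'%s' is not a TIFF file", path)
  ifd_off <- rd(bytes[5:8])
  if (ifd_off + 1L > length(bytes)) stop_io("truncated TIFF file '%s'", path)
  n_entries <- rd(bytes[(ifd_off + 1L):(ifd_off + 2L)])
  tags <- list()
  for (e in seq_len(n_entries)) {
    off <- ifd_off + 2L + (e - 1L) * 12L
    if (off + 12L > length(bytes)) stop_io("truncated TIFF IFD in '%s'", path)
    tag <- rd(bytes[(off + 1L):(off + 2L)])
    type <- rd(bytes[(off + 3L):(off + 4L)])
    count <- rd(bytes[(off + 5L):(off + 8L)])
    type_size <- c(1L, 1L, 2L, 4L)[type]  # BYTE, ASCII, SHORT, LONG
    if (is.na(type_size)) { tags[[as.character(tag)]] <- NULL; next }
    nbytes <- type_size * count
    vraw <- if (nbytes <= 4L) bytes[(off + 9L):(off + 8L + nbytes)] else {
      voff <- rd(bytes[(off + 9L):(off + 12L)])
      if (voff + nbytes > length(bytes)) stop_io("truncated TIFF in '%s'", path)
      bytes[(voff + 1L):(voff + nbytes)]
    }
    vals <- vapply(seq_len(count), function(i) {
      rd(vraw[((i - 1L) * type_size + 1L):(i * type_size)])
    }, numeric(1))
    tags[[as.character(tag)]] <- vals
  }
  need <- function(tag, default = NULL) {
    v <- tags[[as.character(tag)]]
    if (is.null(v)) {
      if (is.null(default)) stop_io("TIFF tag %d missing in '%s'", tag, path)
      default
    } else v
  }
  width <- need(256L); height <- need(257L)
  bits <- need(258L, 8L); compression <- need(259L, 1L)
  spp <- need(277L, 1L)
  offsets <- need(273L); counts <- need(279L)
  rows_per_strip <- need(278L, height)
  if (compression != 1) {
    stop_io("compressed TIFF (%d) not supported: '%s'", compression, path)
  }
  if (!all(bits %in% c(8, 16)) || length(unique(bits)) != 1L) {
    stop_io("unsupported TIFF bit depth in '%s'", path)
  }
  bits <- bits[1L]
  if (!spp %in% c(1, 3)) {
    stop_io("unsupported TIFF samples per pixel %d in '%s'", spp, path)
  }
  bytes_per_sample <- bits %/% 8L
  pix <- numeric(width * height * spp)
  filled <- 0L
  for (s in seq_along(offsets)) {
    cnt <- counts[s]
    if (offsets[s] + cnt > length(bytes)) {
      stop_io("truncated TIFF pixel data in '%s'", path)
    }
    strip <- bytes[(offsets[s] + 1L):(offsets[s] + cnt)]
    v <- as.numeric(strip)
    if (bytes_per_sample == 2L) {
      first <- v[seq(1L, length(v), by = 2L)]
      second <- v[seq(2L, length(v), by = 2L)]
      v <- if (le) second * 256 + first else first * 256 + second
    }
    pix[(filled + 1L):(filled + length(v))] <- v
    filled <- filled + length(v)
  }
  if (filled < width * height * spp) {
    stop_io("truncated TIFF pixel data in '%s'", path)
  }
  if (bits == 16L) pix <- pix / 65535 * 255
  if (spp == 3L) {
    r <- pix[seq(1L, length(pix), by = 3L)]
    g <- pix[seq(2L, length(pix), by = 3L)]
    b <- pix[seq(3L, length(pix), by = 3L)]
    pix <- 0.299 * r + 0.587 * g + 0.114 * b
  }
  matrix(pix, nrow = height, ncol = width, byrow = TRUE)
}
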