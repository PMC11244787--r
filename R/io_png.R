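# Self-contained 8-bit grayscale PNG codec.
#
# The deflate layer is base R's memCompress()/memDecompress(), which emit
# and accept zlib streams -- exactly the format PNG's IDAT chunks carry.
# Only the chunk framing, CRC32 and scanline (un)filtering live here.
# Reading supports the common still-image layouts: bit depth 8/16, color
# types 0 (gray), 2 (RGB), 4 (gray+alpha), 6 (RGBA), non-interlaced.

.png_signature <- as.raw(c(0x89, 0x50, 0x4E, 0x47, 0x0D, 0x0A, 0x1A, 0x0A))

.crc_table <- local({
  tab <- integer(256L)
  for (n in 0:255) {
    c <- n
    for (k in 1:8) {
      c <- if (bitwAnd(c, 1L) != 0L) {
        bitwXor(-306674912L, bitwShiftR(bitwAnd(c, -2L), 1L))  # 0xEDB88320
      } else {
        bitwShiftR(bitwAnd(c, -2L), 1L)
      }
    }
    tab[n + 1L] <- c
  }
  tab
})

crc32 <- function(bytes) {
  crc <- -1L  # 0xFFFFFFFF
  b <- as.integer(bytes)
  for (i in seq_along(b)) {
    idx <- bitwAnd(bitwXor(crc, b[i]), 255L)
    crc <- bitwXor(bitwShiftR(bitwAnd(crc, -256L), 8L), .crc_table[idx + 1L])
  }
  bitwXor(crc, -1L)
}

# big-endian u32 <-> raw helpers (values < 2^31, enough for chunk lengths)
u32_raw <- function(x) {
  x <- as.numeric(x)
  if (x < 0) x <- x + 4294967296
  as.raw(c(x %/% 16777216, (x %/% 65536) %% 256, (x %/% 256) %% 256, x %% 256))
}
raw_u32 <- function(r) sum(as.numeric(r) * c(16777216, 65536, 256, 1))

png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  c(u32_raw(length(data)), body, u32_raw(crc32(body)))
}

# img: integer matrix in [0,255], rows = image rows
png_write_gray <- function(img, path) {
  m <- nrow(img); n <- ncol(img)
  ihdr <- c(u32_raw(n), u32_raw(m),
            as.raw(c(8L, 0L, 0L, 0L, 0L)))  # depth 8, gray, deflate, no interlace
  # scanline stream: one filter-type-0 byte, then n pixel bytes, per row
  scan <- matrix(as.raw(0L), n + 1L, m)
  scan[-1L, ] <- as.raw(t(img))
  idat <- memCompress(as.vector(scan), type = "gzip")
  out <- c(.png_signature,
           png_chunk("IHDR", ihdr),
           png_chunk("IDAT", idat),
           png_chunk("IEND", raw(0)))
  ok <- tryCatch({ writeBin(out, path); TRUE }, error = function(e) FALSE,
                 warning = function(w) FALSE)
  if (!ok) stop_io("cannot write PNG file '%s'", path)
  invisible(path)
}

# Returns a numeric matrix on [0,255] (luminance for color inputs).
png_read <- function(path) {
  size <- file.info(path)$size
  bytes <- readBin(path, "raw", n = size)
  if (length(bytes) < 8L || !identical(bytes[1:8], .png_signature)) {
    stop_io("'%s' is not a PNG file", path)
  }
  pos <- 9L
  ihdr <- NULL
  idat <- list()
  seen_iend <- FALSE
  while (pos + 7L <= length(bytes)) {
    len <- raw_u32(bytes[pos:(pos + 3L)])
    typ <- rawToChar(bytes[(pos + 4L):(pos + 7L)])
    dat_end <- pos + 7L + len
    if (dat_end + 4L > length(bytes)) stop_io("truncated PNG file '%s'", path)
    dat <- if (len > 0L) bytes[(pos + 8L):dat_end] else raw(0)
    if (typ == "IHDR") ihdr <- dat
    else if (typ == "IDAT") idat[[length(idat) + 1L]] <- dat
    else if (typ == "IEND") { seen_iend <- TRUE; break }
    pos <- dat_end + 5L
  }
  if (is.null(ihdr) || !seen_iend || length(idat) == 0L) {
    stop_io("truncated or malformed PNG file '%s'", path)
  }
  width <- raw_u32(ihdr[1:4]); height <- raw_u32(ihdr[5:8])
  depth <- as.integer(ihdr[9]); ctype <- as.integer(ihdr[10])
  interlace <- as.integer(ihdr[13])
  if (width < 1 || height < 1) stop_io("zero-sized PNG '%s'", path)
  if (interlace != 0L) stop_io("interlaced PNG not supported: '%s'", path)
  if (!depth %in% c(8L, 16L)) {
    stop_io("unsupported PNG bit depth %d in '%s'", depth, path)
  }
  channels <- switch(as.character(ctype),
                     "0" = 1L, "2" = 3L, "4" = 2L, "6" = 4L,
                     stop_io("unsupported PNG color type %d in '%s'",
                             ctype, path))
  raw_stream <- tryCatch(
    memDecompress(do.call(c, idat), type = "gzip"),
    error = function(e) stop_io("corrupt PNG data in '%s'", path))
  bpp <- channels * depth %/% 8L
  stride <- width * bpp
  if (length(raw_stream) < height * (stride + 1L)) {
    stop_io("truncated PNG pixel data in '%s'", path)
  }
  recon <- png_unfilter(raw_stream, height, stride, bpp)
  # recon: height x stride integer matrix of reconstructed bytes
  if (depth == 16L) {
    hi <- recon[, seq(1L, stride, by = 2L), drop = FALSE]
    lo <- recon[, seq(2L, stride, by = 2L), drop = FALSE]
    samples <- (hi * 256 + lo) / 65535 * 255
    ncol_s <- stride %/% 2L
  } else {
    samples <- recon
    ncol_s <- stride
  }
  if (channels == 1L) return(samples[, , drop = FALSE])
  cols <- seq(1L, ncol_s, by = channels)
  if (channels == 2L) return(samples[, cols, drop = FALSE])
  r <- samples[, cols, drop = FALSE]
  g <- samples[, cols + 1L, drop = FALSE]
  b <- samples[, cols + 2L, drop = FALSE]
  0.299 * r + 0.587 * g + 0.114 * b  # Rec.601 luminance
}

# Undo PNG scanline filters 0-4; returns height x stride integer matrix.
png_unfilter <- function(stream, height, stride, bpp) {
  ints <- as.integer(stream)
  out <- matrix(0L, height, stride)
  prev <- integer(stride)
  for (row in seq_len(height)) {
    off <- (row - 1L) * (stride + 1L)
    ft <- ints[off + 1L]
    cur <- ints[(off + 2L):(off + 1L + stride)]
    rec <- switch(as.character(ft),
      "0" = cur,
      "1" = {  # Sub: per-byte-lane cumulative sum mod 256
        r <- cur
        for (lane in seq_len(bpp)) {
          idx <- seq(lane, stride, by = bpp)
          r[idx] <- cumsum(cur[idx]) %% 256L
        }
        r
      },
      "2" = (cur + prev) %% 256L,  # Up
      "3" = {  # Average
        r <- integer(stride)
        for (i in seq_len(stride)) {
          left <- if (i > bpp) r[i - bpp] else 0L
          r[i] <- (cur[i] + (left + prev[i]) %/% 2L) %% 256L
        }
        r
      },
      "4" = {  # Paeth
        r <- integer(stride)
        for (i in seq_len(stride)) {
          a <- if (i > bpp) r[i - bpp] else 0L
          b <- prev[i]
          cc <- if (i > bpp) prev[i - bpp] else 0L
          p <- a + b - cc
          pa <- abs(p - a); pb <- abs(p - b); pc <- abs(p - cc)
          pred <- if (pa <= pb && pa <= pc) a else if (pb <= pc) b else cc
          r[i] <- (cur[i] + pred) %% 256L
        }
        r
      },
      stop_io("invalid PNG filter type %d", ft))
    out[row, ] <- rec
    prev <- rec
  }
  out
}
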