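#' Read a grayscale image from disk
#'
#' Decodes an 8- or 16-bit PNG or uncompressed TIFF. Color images are
#' converted to luminance with the Rec.601 weights (0.299 R + 0.587 G +
#' 0.114 B); 16-bit samples are rescaled to \[0, 255\]. The format is
#' detected from the file's magic bytes, not its extension.
#'
#' @param path path to an existing image file.
#' @return a [gray_image] with range tag `"raw8"`.
#' @seealso [write_image()]
#' @export
read_image <- function(path) {
  if (!is.character(path) || length(path) != 1L) {
    stop_validation("path must be a single string")
  }
  if (!file.exists(path)) stop_io("file not found: '%s'", path)
  if (isTRUE(file.info(path)$isdir)) stop_io("'%s' is a directory", path)
  magic <- readBin(path, "raw", n = 4L)
  pix <- if (length(magic) >= 4L && identical(magic, .png_signature[1:4])) {
    png_read(path)
  } else if (length(magic) >= 2L &&
             rawToChar(magic[1:2]) %in% c("II", "MM")) {
    tiff_read(path)
  } else {
    stop_io("'%s' is not a recognized PNG or TIFF file", path)
  }
  if (nrow(pix) < 2L || ncol(pix) < 2L) {
    stop_validation("image in '%s' is smaller than 2x2", path)
  }
  gray_image(pmin(pmax(pix, 0), 255), "raw8")
}

#' Write a grayscale image to disk
#'
#' Writes an 8-bit single-channel PNG or uncompressed TIFF, chosen by the
#' file extension (`.png` default; `.tif`/`.tiff` for TIFF). Unit-range
#' images are scaled by 255; intensities are quantized round-half-up, so
#' `read_image(write_image(x, p))` reproduces a raw8 integer image exactly.
#'
#' @param img a [gray_image].
#' @param path destination path; the directory must exist.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  if (!is_gray_image(img)) stop_validation("img must be a gray_image")
  if (!is.character(path) || length(path) != 1L) {
    stop_validation("path must be a single string")
  }
  dir <- dirname(path)
  if (!dir.exists(dir)) stop_io("directory does not exist: '%s'", dir)
  pix <- img$pixels
  if (img$range == "unit") pix <- pix * 255
  q <- round_half_up(pix)
  q[q < 0] <- 0; q[q > 255] <- 255
  storage.mode(q) <- "integer"
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) tiff_write_gray(q, path)
  else png_write_gray(q, path)
  invisible(path)
}
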