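#' Grayscale image container
#'
#' The universal carrier between pipeline stages: a numeric matrix of
#' intensities together with an explicit range tag. `"raw8"` images live on
#' \[0, 255\] (the native scale of 8-bit sources; values need not be
#' integers, e.g. a fused image before quantization), `"unit"` images on
#' \[0, 1\] (the normalized scale every filtering stage operates on).
#'
#' @param pixels numeric matrix, at least 2x2, all values finite and within
#'   the declared range.
#' @param range one of `"raw8"` or `"unit"`.
#' @return an object of class `gray_image`.
#' @examples
#' img <- gray_image(matrix(0:3 * 85, 2, 2), "raw8")
#' range_tag(img)
#' @export
gray_image <- function(pixels, range = c("raw8", "unit")) {
  range <- match.arg(range)
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop_validation("pixels must be a numeric matrix")
  }
  if (nrow(pixels) < 2L || ncol(pixels) < 2L) {
    stop_validation("image must be at least 2x2, got %dx%d",
                    nrow(pixels), ncol(pixels))
  }
  if (any(!is.finite(pixels))) {
    stop_validation("image contains non-finite pixels")
  }
  hi <- if (range == "raw8") 255 else 1
  if (min(pixels) < 0 || max(pixels) > hi) {
    stop_validation(
      "pixel values [%g, %g] outside declared '%s' range [0, %g]",
      min(pixels), max(pixels), range, hi)
  }
  storage.mode(pixels) <- "double"
  structure(list(pixels = pixels, range = range), class = "gray_image")
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image %dx%d, range %s, values [%.4g, %.4g]>\n",
              nrow(x$pixels), ncol(x$pixels), x$range,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.gray_image <- function(x) dim(x$pixels)

#' @export
as.matrix.gray_image <- function(x, ...) x$pixels

#' @rdname gray_image
#' @param x object to test or query.
#' @export
is_gray_image <- function(x) inherits(x, "gray_image")

#' @rdname gray_image
#' @export
range_tag <- function(x) {
  if (!is_gray_image(x)) stop_validation("not a gray_image")
  x$range
}

# Coerce to a pixel matrix; `range`, when given, enforces the tag for
# gray_image inputs (bare matrices are trusted to be on that scale).
as_pixels <- function(x, range = NULL, arg = "image") {
  if (is_gray_image(x)) {
    if (!is.null(range) && x$range != range) {
      stop_validation("%s must be a '%s' image, got '%s'", arg, range, x$range)
    }
    return(x$pixels)
  }
  if (is.matrix(x) && is.numeric(x)) return(x)
  stop_validation("%s must be a gray_image or numeric matrix", arg)
}

check_same_shape <- function(a, b, what = "images") {
  da <- if (is_gray_image(a)) dim(a$pixels) else dim(a)
  db <- if (is_gray_image(b)) dim(b$pixels) else dim(b)
  if (!identical(da, db)) {
    stop_validation("%s differ in shape: %dx%d vs %dx%d",
                    what, da[1L], da[2L], db[1L], db[2L])
  }
  invisible(TRUE)
}
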