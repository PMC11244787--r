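#' Gradient-magnitude approximation
#'
#' Forward differences `dx = t(i, j+1) - t(i, j)` (horizontal) and
#' `dy = t(i+1, j) - t(i, j)` (vertical), zero at the last column/row.
#' `mode = "paper"` combines them as `|dx - dy|` (the published form,
#' which vanishes on exact 45-degree diagonal ramps); `mode = "l1"` uses
#' the conventional `|dx| + |dy|` magnitude, provided as the robust
#' alternative.
#'
#' @param t_bar a [gray_image] or numeric matrix.
#' @param mode `"paper"` (default) or `"l1"`.
#' @return non-negative magnitude matrix `M`.
#' @export
gradient_magnitude <- function(t_bar, mode = c("paper", "l1")) {
  mode <- match.arg(mode)
  t <- as_pixels(t_bar, arg = "t_bar")
  m <- nrow(t); n <- ncol(t)
  dx <- cbind(t[, -1L, drop = FALSE] - t[, -n, drop = FALSE], 0)
  dy <- rbind(t[-1L, , drop = FALSE] - t[-m, , drop = FALSE], 0)
  if (mode == "paper") abs(dx - dy) else abs(dx) + abs(dy)
}

#' Signed decision map
#'
#' `D = M_A - M_B`: positive where source A carries the sharper local
#' change, negative where source B does.
#'
#' @param M_A,M_B gradient-magnitude matrices of identical shape.
#' @return signed matrix `D`.
#' @export
decision_map <- function(M_A, M_B) {
  if (!is.matrix(M_A) || !is.matrix(M_B)) {
    stop_validation("M_A and M_B must be matrices")
  }
  check_same_shape(M_A, M_B, "magnitude maps")
  M_A - M_B
}

#' Square mean filter
#'
#' Averages over an odd `window x window` neighborhood with replicate
#' padding, spreading the influence of strong-gradient pixels to their
#' neighbors before binarization.
#'
#' @param D numeric matrix.
#' @param window odd window side, >= 1.
#' @return the locally averaged matrix.
#' @export
mean_filter <- function(D, window = 7L) {
  if (!is.matrix(D) || !is.numeric(D)) stop_validation("D must be a matrix")
  window <- as.integer(window)
  if (is.na(window) || window < 1L || window %% 2L == 0L) {
    stop_validation("window must be an odd integer >= 1, got %d", window)
  }
  if (window == 1L) return(D)
  box_mean(D, (window - 1L) %/% 2L)
}

#' Binarize a smoothed decision map
#'
#' Strict step function: 1 where the value is positive, 0 otherwise
#' (ties at exactly zero select source B).
#'
#' @param D_mean numeric matrix.
#' @return a 0/1 matrix.
#' @export
binarize <- function(D_mean) {
  if (!is.numeric(D_mean)) stop_validation("D_mean must be numeric")
  (D_mean > 0) + 0
}

#' Salient structure extraction
#'
#' Compares the gradient magnitudes of two processed images, smooths the
#' signed difference with a mean filter, and binarizes, yielding the
#' binary map of where source A dominates. Antisymmetric in its inputs:
#' swapping A and B negates `D` exactly.
#'
#' @param t_A,t_B processed [gray_image]s (or matrices) of equal shape.
#' @param window odd mean-filter side; default 7.
#' @param mode gradient mode, see [gradient_magnitude()].
#' @return list of class `decision_result` with `M_A`, `M_B`, `D`,
#'   `D_mean`, `I_A`, `window`, `mode`.
#' @export
extract_salient_structure <- function(t_A, t_B, window = 7L,
                                      mode = c("paper", "l1")) {
  mode <- match.arg(mode)
  a <- as_pixels(t_A, arg = "t_A"); b <- as_pixels(t_B, arg = "t_B")
  check_same_shape(a, b)
  M_A <- gradient_magnitude(a, mode)
  M_B <- gradient_magnitude(b, mode)
  D <- decision_map(M_A, M_B)
  D_mean <- mean_filter(D, window)
  structure(list(M_A = M_A, M_B = M_B, D = D, D_mean = D_mean,
                 I_A = binarize(D_mean),
                 window = as.integer(window), mode = mode),
            class = "decision_result")
}

#' @export
print.decision_result <- function(x, ...) {
  cat(sprintf(
    "<decision_result %dx%d, window %d, mode %s, A-selected %.1f%%>\n",
    nrow(x$D), ncol(x$D), x$window, x$mode, 100 * mean(x$I_A)))
  invisible(x)
}
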