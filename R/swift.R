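#' Parameters of the swift contrast algorithm
#'
#' @param lambda_tune positive integer tuning exponent of the second
#'   adjustment function (`eta = u^lambda / lambda!`); default 3.
#' @param gamma enhancement attenuation factor, > 0 (larger values give a
#'   flatter, less-bright enhancement); default 1.
#' @param parse_mode how the nonlinear tone-mapping expression is grouped:
#'   `"fraction"` (default) evaluates
#'   `f = exp((tan u - sigma) / (gamma * (exp(u) - eta)))`; `"literal"`
#'   evaluates `f = exp(tan u - sigma * exp(u) - eta)^gamma`. Both are
#'   kept because the published layout of the expression is ambiguous;
#'   the downstream min-max rescale makes them largely equivalent in
#'   practice.
#' @return a validated list of class `swift_params`.
#' @export
swift_params <- function(lambda_tune = 3L, gamma = 1.0,
                         parse_mode = c("fraction", "literal")) {
  parse_mode <- match.arg(parse_mode)
  lambda_tune <- as.integer(lambda_tune)
  if (is.na(lambda_tune) || lambda_tune < 1L) {
    stop_validation("lambda_tune must be a positive integer")
  }
  if (!is_scalar_num(gamma) || gamma <= 0) {
    stop_validation("gamma must be > 0")
  }
  structure(list(lambda_tune = lambda_tune, gamma = gamma,
                 parse_mode = parse_mode), class = "swift_params")
}

#' Logarithmic compression
#'
#' `u = ln(1 + G)` per pixel; maps the unit range onto `[0, ln 2]`,
#' damping excessive intensities before tone mapping.
#'
#' @param G a unit [gray_image] or matrix on \[0, 1\].
#' @return numeric matrix `u`.
#' @export
log_compress <- function(G) {
  g <- as_pixels(G, range = "unit", arg = "G")
  if (min(g) < 0 || max(g) > 1) stop_validation("G must lie in [0, 1]")
  log1p(g)
}

#' Contrast adjustment factor (corrected sample standard deviation)
#'
#' The spread of the log-compressed image: low-contrast images score low,
#' high-contrast images high. Uses the n-1 denominator.
#'
#' @param u numeric matrix (log-compressed image).
#' @return scalar `sigma >= 0`.
#' @export
adjustment_sigma <- function(u) {
  if (!is.numeric(u)) stop_validation("u must be numeric")
  if (length(u) < 2L) {
    stop_validation("adjustment factor needs at least 2 pixels")
  }
  stats::sd(as.vector(u))
}

#' Second adjustment function
#'
#' `eta = u^lambda / lambda!` element-wise; monotone non-decreasing in
#' `u` for `u >= 0`.
#'
#' @param u numeric matrix.
#' @param lambda_tune positive integer exponent.
#' @return matrix `eta`, same shape as `u`.
#' @export
adjustment_eta <- function(u, lambda_tune = 3L) {
  lambda_tune <- as.integer(lambda_tune)
  if (is.na(lambda_tune) || lambda_tune < 1L) {
    stop_validation("lambda_tune must be a positive integer")
  }
  u^lambda_tune / factorial(lambda_tune)
}

#' Nonlinear tone mapping
#'
#' Applies the swift curve combining the tangent (radians) of the
#' log-compressed intensities with the two adjustment factors; see
#' [swift_params()] for the two supported groupings. For `u` in
#' `[0, ln 2]` and `lambda_tune = 3` the fraction-mode denominator
#' `exp(u) - eta >= 1 - ln(2)^3/6 > 0`, so no singularity can occur.
#'
#' @param u numeric matrix from [log_compress()].
#' @param sigma scalar from [adjustment_sigma()].
#' @param eta matrix from [adjustment_eta()].
#' @param params a [swift_params].
#' @return the tone-mapped matrix `f`.
#' @export
tone_map <- function(u, sigma, eta, params = swift_params()) {
  if (!inherits(params, "swift_params")) {
    params <- do.call(swift_params, as.list(params))
  }
  f <- if (params$parse_mode == "fraction") {
    exp((tan(u) - sigma) / (params$gamma * (exp(u) - eta)))
  } else {
    exp(tan(u) - sigma * exp(u) - eta)^params$gamma
  }
  if (any(!is.finite(f))) {
    bad <- which(!is.finite(f), arr.ind = TRUE)[1L, ]
    stop_numeric("tone mapping produced a non-finite value at pixel (%d, %d)",
                 bad[1L], bad[2L])
  }
  f
}

#' Restore the dynamic range
#'
#' Min-max rescaling of the tone-mapped image back onto \[0, 1\]; a
#' constant input (zero dynamic range) maps to the mid-gray 0.5 by
#' convention.
#'
#' @param f numeric matrix.
#' @return a unit [gray_image].
#' @export
rescale_dynamic_range <- function(f) {
  if (!is.matrix(f) || !is.numeric(f)) stop_validation("f must be a matrix")
  if (any(!is.finite(f))) stop_validation("f contains non-finite values")
  lo <- min(f); hi <- max(f)
  out <- if (hi > lo) (f - lo) / (hi - lo) else matrix(0.5, nrow(f), ncol(f))
  gray_image(pmin(pmax(out, 0), 1), "unit")
}

#' Swift contrast enhancement
#'
#' Full chain: logarithmic compression, statistical adjustment factors,
#' nonlinear tone mapping, dynamic-range restoration. Deterministic.
#'
#' @param G a unit [gray_image].
#' @param params a [swift_params].
#' @return list of class `swift_result` with `image` (enhanced unit
#'   [gray_image]) and `intermediates` (`u`, `sigma_adj`, `u_bar`, `eta`,
#'   `f`) for inspection.
#' @examples
#' G <- gray_image(matrix(seq(0, 1, length.out = 16), 4, 4), "unit")
#' enh <- swift_enhance(G)
#' range(as.matrix(enh$image))
#' @export
swift_enhance <- function(G, params = swift_params()) {
  g <- as_pixels(G, range = "unit", arg = "G")
  if (!inherits(params, "swift_params")) {
    params <- do.call(swift_params, as.list(params))
  }
  u <- log_compress(gray_image(g, "unit"))
  sigma <- adjustment_sigma(u)
  eta <- adjustment_eta(u, params$lambda_tune)
  f <- tone_map(u, sigma, eta, params)
  out <- rescale_dynamic_range(f)
  structure(list(image = out,
                 intermediates = list(u = u, sigma_adj = sigma,
                                      u_bar = mean(u), eta = eta, f = f),
                 params = params),
            class = "swift_result")
}

#' @export
print.swift_result <- function(x, ...) {
  cat(sprintf("<swift_result %dx%d, sigma_adj %.4f, mode %s>\n",
              nrow(x$image$pixels), ncol(x$image$pixels),
              x$intermediates$sigma_adj, x$params$parse_mode))
  invisible(x)
}
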