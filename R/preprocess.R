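#' Normalize an 8-bit image to the unit range
#'
#' Divides intensities by 255, the first step of the pipeline. Feeding an
#' already-normalized image is rejected to guard against accidental
#' double normalization.
#'
#' @param S a raw8 [gray_image].
#' @return a unit-range [gray_image] `G = S / 255`.
#' @export
normalize_image <- function(S) {
  if (!is_gray_image(S)) stop_validation("S must be a gray_image")
  if (S$range != "raw8") {
    stop_validation("image is already unit-range; refusing to normalize twice")
  }
  gray_image(S$pixels / 255, "unit")
}

#' Parameters of the adaptive local Wiener filter
#'
#' @param radius half-width of the square filtering window (side
#'   `2 * radius + 1`); default 3, the setting used for CT/MRI pairs. The
#'   ablation alternative of 7 is available by overriding.
#' @param lam regularization weight `lambda` penalizing the per-pixel gain;
#'   default 0.01. `lam = 0` disables smoothing entirely.
#' @return a validated list of class `wiener_params`.
#' @export
wiener_params <- function(radius = 3L, lam = 0.01) {
  radius <- as.integer(radius)
  if (is.na(radius) || radius < 1L) stop_validation("radius must be >= 1")
  if (!is_scalar_num(lam) || lam < 0) {
    stop_validation("lam must be >= 0, got %s", format(lam))
  }
  structure(list(radius = radius, lam = lam), class = "wiener_params")
}

#' Local window mean and variance
#'
#' Per-pixel mean and population variance over a `(2*radius+1)^2` square
#' window with edge-replicated padding, computed from separable box sums
#' so the per-pixel cost is independent of the radius.
#'
#' @param G a unit [gray_image] or numeric matrix.
#' @param radius window half-width, >= 1.
#' @return list with matrices `mean_map` and `var_map` (var >= 0).
#' @export
local_stats <- function(G, radius = 3L) {
  g <- as_pixels(G, arg = "G")
  radius <- as.integer(radius)
  if (is.na(radius) || radius < 1L) stop_validation("radius must be >= 1")
  mu <- box_mean(g, radius)
  m2 <- box_mean(g * g, radius)
  v <- m2 - mu * mu
  v[v < 0] <- 0  # guard tiny negative round-off
  list(mean_map = mu, var_map = v)
}

#' Adaptive local Wiener filtering
#'
#' Edge-preserving denoising: each pixel is pulled toward its local window
#' mean with a data-driven gain
#' \deqn{\bar G = \mu_w + k (G - \mu_w), \quad k = \sigma^2_w / (\sigma^2_w + \lambda).}
#' In flat regions the window variance is small, `k ~ 0` and the output is
#' the local mean (noise suppressed); on strong structure the variance
#' dominates `lambda`, `k ~ 1` and the pixel passes through (edges kept).
#' Since `0 <= k <= 1` the output is a pixel-wise convex combination of
#' `G` and its local mean.
#'
#' @param G a unit [gray_image].
#' @param params a [wiener_params].
#' @return the filtered unit [gray_image].
#' @export
wiener_filter <- function(G, params = wiener_params()) {
  g <- as_pixels(G, range = "unit", arg = "G")
  if (!inherits(params, "wiener_params")) {
    params <- do.call(wiener_params, as.list(params))
  }
  st <- local_stats(g, params$radius)
  denom <- st$var_map + params$lam
  k <- ifelse(denom > 0, st$var_map / denom, 0)
  out <- st$mean_map + k * (g - st$mean_map)
  out[k == 1] <- g[k == 1]  # lambda = 0: exact pass-through, no round-off
  # k in [0,1] keeps the result inside [min(G, mu), max(G, mu)] analytically;
  # clip only floating-point excursions
  out <- pmin(pmax(out, 0), 1)
  gray_image(out, "unit")
}
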