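#' Parameters of the normalized-convolution edge-aware filter
#'
#' @param sigma_s spatial scale in pixels (> 0); default 30.
#' @param sigma_r range (intensity) scale on the unit scale; finite
#'   positive values make guidance edges block smoothing, `Inf`
#'   degenerates the filter to a purely spatial one. Default 0.25.
#' @param iterations number of box-filtering iterations `T` (>= 1);
#'   default 3, after which the spatial filter is visually
#'   indistinguishable from a Gaussian of std `sigma_s`.
#' @return a validated list of class `nc_params`.
#' @export
nc_params <- function(sigma_s = 30, sigma_r = 0.25, iterations = 3L) {
  if (!is.numeric(sigma_s) || length(sigma_s) != 1L || !is.finite(sigma_s) ||
      sigma_s <= 0) {
    stop_validation("sigma_s must be a positive finite scalar")
  }
  if (!is.numeric(sigma_r) || length(sigma_r) != 1L || is.na(sigma_r) ||
      sigma_r <= 0) {
    stop_validation("sigma_r must be positive (possibly Inf)")
  }
  iterations <- as.integer(iterations)
  if (is.na(iterations) || iterations < 1L) {
    stop_validation("iterations must be >= 1")
  }
  structure(list(sigma_s = sigma_s, sigma_r = sigma_r,
                 iterations = iterations), class = "nc_params")
}

#' Domain transform of a scan line
#'
#' Warps the coordinates of a 1-D scan line so that Euclidean distance in
#' the transformed domain equals the edge-aware (geodesic) distance in
#' the original one:
#' \deqn{ct(x) = \sum_{k \le x} \big(1 + (\sigma_s/\sigma_r)\,|g(k) - g(k-1)|\big),}
#' using backward differences of the guidance intensities, with
#' `ct(1) = 0`. Monotone non-decreasing by construction; for
#' `sigma_r = Inf` it reduces to unit spacing `0, 1, 2, ...`.
#'
#' @param guidance_line numeric vector of guidance intensities on \[0, 1\].
#' @param sigma_s,sigma_r spatial and range scales (> 0; `sigma_r` may be
#'   `Inf`).
#' @return numeric vector `ct`, same length as the input.
#' @export
domain_transform <- function(guidance_line, sigma_s, sigma_r) {
  if (!is.numeric(guidance_line) || length(guidance_line) < 1L) {
    stop_validation("guidance_line must be a non-empty numeric vector")
  }
  if (!is_scalar_num(sigma_s) || sigma_s <= 0) {
    stop_validation("sigma_s must be > 0")
  }
  if (!is.numeric(sigma_r) || length(sigma_r) != 1L || is.na(sigma_r) ||
      sigma_r <= 0) {
    stop_validation("sigma_r must be > 0 (possibly Inf)")
  }
  n <- length(guidance_line)
  if (n == 1L) return(0)
  ratio <- if (is.infinite(sigma_r)) 0 else sigma_s / sigma_r
  inc <- 1 + ratio * abs(diff(guidance_line))
  c(0, cumsum(inc))
}

#' Per-iteration spatial scales of the iterated box filter
#'
#' Decreasing schedule
#' \deqn{\sigma_{Hi} = \sigma_s \sqrt{3}\, 2^{T-i} / \sqrt{4^T - 1},}
#' chosen so the iteration variances sum to `sigma_s^2` and the composed
#' box filters converge on a Gaussian of std `sigma_s`.
#'
#' @param sigma_s total spatial scale.
#' @param T number of iterations, >= 1.
#' @return numeric vector of length `T`.
#' @export
sigma_schedule <- function(sigma_s, T = 3L) {
  T <- as.integer(T)
  if (is.na(T) || T < 1L) stop_validation("T must be >= 1")
  if (!is_scalar_num(sigma_s) || sigma_s <= 0) {
    stop_validation("sigma_s must be > 0")
  }
  sigma_s * sqrt(3) * 2^(T - seq_len(T)) / sqrt(4^T - 1)
}

#' Normalized-convolution box filter along one scan line
#'
#' Averages every sample over the neighbors whose transformed coordinate
#' lies within `r`:
#' \deqn{out(p) = \frac{1}{K_p} \sum_{q:\ |ct(p)-ct(q)| \le r} s(q),}
#' with `K_p` the number of such neighbors. Because `ct` is monotone the
#' window slides forward only, so a two-pointer sweep evaluates all
#' samples in O(N) while updating `K_p` per slide; the `"cumsum"` method
#' is a vectorized equivalent used by [nc_smooth()].
#'
#' @param signal numeric vector of sample values.
#' @param ct non-decreasing transformed coordinates, same length.
#' @param r box radius in the transformed domain, > 0.
#' @param method `"two_pointer"` (default) or `"cumsum"`.
#' @return filtered numeric vector.
#' @export
nc_box_filter_line <- function(signal, ct, r,
                               method = c("two_pointer", "cumsum")) {
  method <- match.arg(method)
  if (!is.numeric(signal) || !is.numeric(ct) ||
      length(signal) != length(ct)) {
    stop_validation("signal and ct must be numeric vectors of equal length")
  }
  if (is.unsorted(ct)) stop_validation("ct must be non-decreasing")
  if (!is_scalar_num(r) || r <= 0) stop_validation("r must be > 0")
  n <- length(signal)
  if (method == "cumsum") return(nc_line_cumsum(signal, ct, r))
  out <- numeric(n)
  lo <- 1L; hi <- 0L; acc <- 0
  for (p in seq_len(n)) {
    while (hi < n && ct[hi + 1L] <= ct[p] + r) {
      hi <- hi + 1L
      acc <- acc + signal[hi]
    }
    while (ct[lo] < ct[p] - r) {
      acc <- acc - signal[lo]
      lo <- lo + 1L
    }
    out[p] <- acc / (hi - lo + 1L)
  }
  out
}

# vectorized window bounds via findInterval on the monotone ct
nc_line_cumsum <- function(signal, ct, r) {
  cs <- c(0, cumsum(signal))
  hi <- findInterval(ct + r, ct)                    # count of ct(q) <= ct(p)+r
  lo <- findInterval(ct - r, ct, left.open = TRUE)  # count of ct(q) <  ct(p)-r
  (cs[hi + 1L] - cs[lo + 1L]) / (hi - lo)
}

#' Edge-aware smoothing of the salience map
#'
#' Iterated separable normalized convolution: per iteration, every row and
#' then every column of the map is box-filtered in the domain transform of
#' the corresponding guidance scan line, with radius `sqrt(3) * sigma_Hi`
#' so each box matches the variance of its Gaussian counterpart. Guidance
#' edges shrink transformed-domain windows and thereby stop smoothing from
#' bleeding across structure boundaries. The output is a convex average of
#' the input, hence a valid weight map in \[0, 1\] for binary input.
#'
#' @param I_A binary (or \[0, 1\]) matrix to smooth.
#' @param guidance a unit [gray_image] (or matrix on \[0, 1\]) of the same
#'   shape, typically the normalized source image.
#' @param params an [nc_params].
#' @return the smoothed weight-map matrix.
#' @examples
#' g <- matrix(rep(c(0, 1), each = 8), 4, 4)
#' w <- nc_smooth(g, gray_image(g, "unit"), nc_params(sigma_s = 2))
#' range(w)
#' @export
nc_smooth <- function(I_A, guidance, params = nc_params()) {
  if (!inherits(params, "nc_params")) {
    params <- do.call(nc_params, as.list(params))
  }
  x <- as_pixels(I_A, arg = "I_A")
  g <- as_pixels(guidance, range = "unit", arg = "guidance")
  check_same_shape(x, g, "map and guidance")
  sig <- sigma_schedule(params$sigma_s, params$iterations)
  # transforms depend only on the guidance: compute once per direction
  ct_rows <- dt_lines(g, params$sigma_s, params$sigma_r)        # rows
  ct_cols <- dt_lines(t(g), params$sigma_s, params$sigma_r)     # columns
  lo <- min(x); hi <- max(x)
  for (i in seq_len(params$iterations)) {
    r <- sqrt(3) * sig[i]
    x <- nc_pass(x, ct_rows, r)
    x <- t(nc_pass(t(x), ct_cols, r))
  }
  # every pass is a convex average, so the bounds hold analytically;
  # clamp the ~1e-15 cumsum round-off so the weight-map contract is exact
  pmin(pmax(x, lo), hi)
}

# per-row domain transforms of a matrix (list of numeric vectors)
dt_lines <- function(g, sigma_s, sigma_r) {
  ratio <- if (is.infinite(sigma_r)) 0 else sigma_s / sigma_r
  n <- ncol(g)
  inc <- 1 + ratio * abs(g[, -1L, drop = FALSE] - g[, -n, drop = FALSE])
  cum <- if (ncol(inc) == 1L) inc else t(apply(inc, 1L, cumsum))
  ct <- cbind(0, cum)
  lapply(seq_len(nrow(g)), function(i) ct[i, ])
}

nc_pass <- function(x, ct_list, r) {
  out <- x
  for (i in seq_len(nrow(x))) {
    out[i, ] <- nc_line_cumsum(x[i, ], ct_list[[i]], r)
  }
  out
}
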