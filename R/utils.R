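# Internal helpers shared across modules.

stop_validation <- function(...) {
  stop(structure(
    class = c("ncfuse_validation_error", "error", "condition"),
    list(message = sprintf(...), call = sys.call(-1))
  ))
}

stop_io <- function(...) {
  stop(structure(
    class = c("ncfuse_io_error", "error", "condition"),
    list(message = sprintf(...), call = sys.call(-1))
  ))
}

stop_numeric <- function(...) {
  stop(structure(
    class = c("ncfuse_numeric_error", "error", "condition"),
    list(message = sprintf(...), call = sys.call(-1))
  ))
}

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded generators (phantoms, noise) never perturb the
#' global random stream.
#'
#' @param seed integer scalar.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop_validation("seed must be a single finite number, got %s",
                    paste(deparse(seed), collapse = ""))
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

# Replicate-pad a matrix by `r` rows/columns on every side.
pad_replicate <- function(m, r) {
  if (r < 1L) return(m)
  ri <- c(rep(1L, r), seq_len(nrow(m)), rep(nrow(m), r))
  ci <- c(rep(1L, r), seq_len(ncol(m)), rep(ncol(m), r))
  m[ri, ci, drop = FALSE]
}

# Sliding-window sum over a (2*radius+1)^2 square window with replicate
# padding, computed with a summed-area table so per-pixel cost does not
# depend on the radius.
box_sum <- function(m, radius) {
  r <- as.integer(radius)
  p <- pad_replicate(m, r)
  cs <- apply(p, 2L, cumsum)        # cumulative sums down rows
  cs <- t(apply(cs, 1L, cumsum))    # then across columns
  # summed-area table with a leading zero row/column
  sat <- matrix(0, nrow(p) + 1L, ncol(p) + 1L)
  sat[-1L, -1L] <- cs
  i <- seq_len(nrow(m)); j <- seq_len(ncol(m))
  side <- 2L * r + 1L
  sat[i + side, j + side, drop = FALSE] -
    sat[i, j + side, drop = FALSE] -
    sat[i + side, j, drop = FALSE] +
    sat[i, j, drop = FALSE]
}

# Mean over the same sliding window.
box_mean <- function(m, radius) {
  side <- 2L * as.integer(radius) + 1L
  box_sum(m, radius) / (side * side)
}

#' Direct separable Gaussian smoothing
#'
#' Plain 2-D Gaussian convolution with border renormalization (the kernel
#' mass falling outside the image is discarded and the remainder rescaled
#' to sum to one, i.e. normalized convolution with a Gaussian kernel).
#' Serves as the reference filter that the iterated normalized-convolution
#' box filter approximates when the range scale is infinite, and as the
#' band-limiter for phantom textures.
#'
#' @param m numeric matrix.
#' @param sigma Gaussian standard deviation in pixels (> 0).
#' @return numeric matrix of the same shape.
#' @export
gaussian_blur <- function(m, sigma) {
  if (!is.matrix(m) || !is.numeric(m)) {
    stop_validation("gaussian_blur() expects a numeric matrix")
  }
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0) {
    stop_validation("sigma must be a positive scalar")
  }
  rad <- max(1L, as.integer(ceiling(4 * sigma)))
  k <- stats::dnorm(seq(-rad, rad), sd = sigma)
  k <- k / sum(k)
  ones <- matrix(1, nrow(m), ncol(m))
  num <- conv_sep_zero(m, k)
  den <- conv_sep_zero(ones, k)
  num / den
}

# Separable zero-padded convolution with a symmetric 1-D kernel.
conv_sep_zero <- function(m, k) {
  conv_lines <- function(mat, kern) {
    # filter each column of `mat` with `kern`, zero padding
    n <- nrow(mat)
    rad <- (length(kern) - 1L) %/% 2L
    out <- matrix(0, n, ncol(mat))
    for (d in seq_along(kern)) {
      off <- d - 1L - rad
      src <- seq_len(n) + off
      keep <- src >= 1L & src <= n
      out[keep, ] <- out[keep, ] + kern[d] * mat[src[keep], , drop = FALSE]
    }
    out
  }
  t(conv_lines(t(conv_lines(m, k)), k))
}

# round-half-up to integer (base round() is round-half-even)
round_half_up <- function(x) floor(x + 0.5)

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
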