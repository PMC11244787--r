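# Fusion-quality metrics. All operate on the 8-bit intensity scale
# [0, 255]; inputs may be raw8 gray_images or bare matrices on that scale.

metric_pixels <- function(x, arg = "image") {
  p <- if (is_gray_image(x)) {
    if (x$range != "raw8") {
      stop_validation("%s must be a raw8 image for metric evaluation", arg)
    }
    x$pixels
  } else if (is.matrix(x) && is.numeric(x)) x
  else stop_validation("%s must be a gray_image or numeric matrix", arg)
  if (any(!is.finite(p))) stop_validation("%s has non-finite pixels", arg)
  p
}

# integer 0..255 levels for histogram-based metrics
metric_levels <- function(x, arg = "image") {
  p <- round_half_up(metric_pixels(x, arg))
  p[p < 0] <- 0; p[p > 255] <- 255
  storage.mode(p) <- "integer"
  p
}

#' Average pixel intensity
#'
#' Mean intensity of the image, an index of overall brightness/contrast.
#' @param F raw8 [gray_image] or matrix.
#' @return scalar.
#' @export
fm_api <- function(F) mean(metric_pixels(F, "F"))

#' Standard deviation (population)
#'
#' Root of the mean squared deviation from the image mean (denominator
#' `m*n`), measuring the spread of intensities.
#' @inheritParams fm_api
#' @return scalar >= 0.
#' @export
fm_sd <- function(F) {
  p <- metric_pixels(F, "F")
  sqrt(mean((p - mean(p))^2))
}

#' Average gradient
#'
#' Mean Euclidean norm of the forward-difference gradient, a sharpness
#' index. `denom = "valid"` (default) averages over the `(m-1)(n-1)`
#' pixels that have both forward differences; `denom = "mn"` divides by
#' the full pixel count as some formulations print it.
#' @inheritParams fm_api
#' @param denom `"valid"` or `"mn"`.
#' @return scalar >= 0.
#' @export
fm_ag <- function(F, denom = c("valid", "mn")) {
  denom <- match.arg(denom)
  p <- metric_pixels(F, "F")
  m <- nrow(p); n <- ncol(p)
  dx <- p[-m, -n, drop = FALSE] - p[-m, -1L, drop = FALSE]  # horizontal
  dy <- p[-m, -n, drop = FALSE] - p[-1L, -n, drop = FALSE]  # vertical
  s <- sum(sqrt(dx^2 + dy^2))
  s / if (denom == "valid") (m - 1) * (n - 1) else m * n
}

#' Shannon entropy of the intensity histogram
#'
#' `H = -sum p_k log2 p_k` over the 256 integer levels; ranges from 0
#' (constant image) to 8 bits (uniform histogram).
#' @param X raw8 [gray_image] or matrix.
#' @return scalar in \[0, 8\].
#' @export
fm_entropy <- function(X) {
  lev <- metric_levels(X, "X")
  p <- tabulate(lev + 1L, 256L) / length(lev)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Mutual information between two images
#'
#' Computed from the 256x256 joint histogram of integer levels, in bits.
#' Symmetric; `fm_mi(X, X)` equals the entropy of `X`.
#' @param X,Y raw8 [gray_image]s or matrices, same shape.
#' @return scalar >= 0.
#' @export
fm_mi <- function(X, Y) {
  a <- metric_levels(X, "X"); b <- metric_levels(Y, "Y")
  check_same_shape(a, b)
  N <- length(a)
  joint <- tabulate(a * 256L + b + 1L, 65536L)
  pa <- tabulate(a + 1L, 256L) / N
  pb <- tabulate(b + 1L, 256L) / N
  nz <- which(joint > 0L)
  pj <- joint[nz] / N
  ia <- (nz - 1L) %/% 256L + 1L
  ib <- (nz - 1L) %% 256L + 1L
  sum(pj * log2(pj / (pa[ia] * pb[ib])))
}

#' Total mutual information carried into the fused image
#'
#' `MI = MI(A, F) + MI(B, F)`.
#' @param A,B,F raw8 [gray_image]s or matrices, same shape.
#' @return scalar >= 0.
#' @export
fm_mi_total <- function(A, B, F) fm_mi(A, F) + fm_mi(B, F)

#' Spatial frequency
#'
#' Root sum of the row and column frequencies, the RMS of horizontal and
#' vertical neighbor differences (sums normalized by `m*n` as printed in
#' the standard definition).
#' @inheritParams fm_api
#' @return scalar >= 0.
#' @export
fm_sf <- function(F) {
  p <- metric_pixels(F, "F")
  m <- nrow(p); n <- ncol(p)
  rf2 <- sum((p[, -1L, drop = FALSE] - p[, -n, drop = FALSE])^2) / (m * n)
  cf2 <- sum((p[-1L, , drop = FALSE] - p[-m, , drop = FALSE])^2) / (m * n)
  sqrt(rf2 + cf2)
}

pearson_r <- function(x, y, name_x) {
  dx <- x - mean(x); dy <- y - mean(y)
  den <- sqrt(sum(dx^2) * sum(dy^2))
  if (den == 0) {
    stop_validation("correlation undefined: image '%s' (or F) has zero variance",
                    name_x)
  }
  sum(dx * dy) / den
}

#' Correlation coefficient
#'
#' Mean of the Pearson correlations of the fused image with each source:
#' `CC = (r_AF + r_BF) / 2`.
#' @param A,B,F raw8 [gray_image]s or matrices, same shape, non-constant.
#' @return scalar in \[-1, 1\].
#' @export
fm_cc <- function(A, B, F) {
  a <- metric_pixels(A, "A"); b <- metric_pixels(B, "B")
  f <- metric_pixels(F, "F")
  check_same_shape(a, f); check_same_shape(b, f)
  (pearson_r(a, f, "A") + pearson_r(b, f, "B")) / 2
}

#' Fusion symmetry
#'
#' How evenly the fused image's mutual information splits between the two
#' sources: `FS = 2 - |MI_AF / (MI_AF + MI_BF) - 0.5|`, in \[1.5, 2\]
#' with 2 at a perfectly even split.
#' @inheritParams fm_cc
#' @return scalar in \[1.5, 2\].
#' @export
fm_fs <- function(A, B, F) {
  mi_af <- fm_mi(A, F); mi_bf <- fm_mi(B, F)
  total <- mi_af + mi_bf
  if (total <= 0) {
    stop_validation("fusion symmetry undefined: total mutual information is 0")
  }
  2 - abs(mi_af / total - 0.5)
}

#' Sobel edge strength and orientation
#'
#' 3x3 Sobel responses with replicate borders; `g = sqrt(sx^2 + sy^2)`,
#' `alpha = atan(sy / sx)` in `(-pi/2, pi/2]` with `alpha = pi/2` for
#' vertical-only response and 0 where both responses vanish.
#' @param X raw8 [gray_image] or matrix.
#' @return list of class `edge_field` with matrices `g` and `alpha`.
#' @export
edge_field <- function(X) {
  p <- pad_replicate(metric_pixels(X, "X"), 1L)
  m <- nrow(p) - 2L; n <- ncol(p) - 2L
  sub <- function(di, dj) p[seq_len(m) + di, seq_len(n) + dj, drop = FALSE]
  # correlation with Gx = [-1 0 1; -2 0 2; -1 0 1] (columns left->right)
  sx <- (sub(0L, 2L) + 2 * sub(1L, 2L) + sub(2L, 2L)) -
        (sub(0L, 0L) + 2 * sub(1L, 0L) + sub(2L, 0L))
  sy <- (sub(2L, 0L) + 2 * sub(2L, 1L) + sub(2L, 2L)) -
        (sub(0L, 0L) + 2 * sub(0L, 1L) + sub(0L, 2L))
  g <- sqrt(sx^2 + sy^2)
  alpha <- matrix(0, m, n)
  nzx <- sx != 0
  alpha[nzx] <- atan(sy[nzx] / sx[nzx])
  alpha[!nzx & sy != 0] <- pi / 2
  structure(list(g = g, alpha = alpha), class = "edge_field")
}

#' Sigmoid constants of the gradient-preservation model
#'
#' The standard constants of the objective gradient-based fusion metric
#' literature, used to map relative edge-strength and orientation
#' agreement onto perceptual preservation scores.
#'
#' @param gamma_g,kappa_g,sigma_g strength-sigmoid constants.
#' @param gamma_a,kappa_a,sigma_a orientation-sigmoid constants.
#' @param L exponent of the perceptual importance weights `w = g^L`.
#' @return a named list.
#' @export
qabf_constants <- function(gamma_g = 0.9994, kappa_g = -15, sigma_g = 0.5,
                           gamma_a = 0.9879, kappa_a = -22, sigma_a = 0.8,
                           L = 1) {
  list(gamma_g = gamma_g, kappa_g = kappa_g, sigma_g = sigma_g,
       gamma_a = gamma_a, kappa_a = kappa_a, sigma_a = sigma_a, L = L)
}

#' Gradient-based fusion quality: transfer, loss, artifacts
#'
#' Per pixel, the relative edge strength `G` and orientation agreement
#' `A` between each source and the fused image are mapped through
#' sigmoids to preservation scores `Q^AF`, `Q^BF`; the overall transfer
#' is their edge-strength-weighted average. Artifact locations are
#' pixels where the fused gradient exceeds both source gradients; the
#' revised artifact measure `Nm` additionally scales them by the local
#' information loss, which makes transfer, loss and revised artifacts
#' exactly complementary:
#' `Q_abf + L_abf + Nm_abf = 1`.
#'
#' The returned `L_abf` is computed from that identity (guaranteeing
#' complementarity); `L_abf_direct`, the restricted sum over
#' non-artifact pixels, is returned for diagnostics and equals `L_abf`
#' analytically.
#'
#' @inheritParams fm_cc
#' @param constants see [qabf_constants()].
#' @return list with `Q_abf`, `L_abf`, `N_abf`, `Nm_abf`,
#'   `L_abf_direct`.
#' @export
gradient_preservation <- function(A, B, F, constants = qabf_constants()) {
  a <- metric_pixels(A, "A"); b <- metric_pixels(B, "B")
  f <- metric_pixels(F, "F")
  check_same_shape(a, f); check_same_shape(b, f)
  ea <- edge_field(a); eb <- edge_field(b); ef <- edge_field(f)
  W <- sum(ea$g^constants$L + eb$g^constants$L)
  if (W == 0) {
    warning("all gradients are zero; preservation is vacuous (Q = 1)")
    return(list(Q_abf = 1, L_abf = 0, N_abf = 0, Nm_abf = 0,
                L_abf_direct = 0))
  }
  q_source <- function(es) {
    # relative strength: smaller/larger, 1 when both zero
    G <- ifelse(es$g > ef$g, ef$g / es$g,
                ifelse(ef$g > 0, es$g / ef$g, 1))
    Aagree <- 1 - abs(es$alpha - ef$alpha) / (pi / 2)
    Qg <- constants$gamma_g /
      (1 + exp(constants$kappa_g * (G - constants$sigma_g)))
    Qa <- constants$gamma_a /
      (1 + exp(constants$kappa_a * (Aagree - constants$sigma_a)))
    Qg * Qa
  }
  Qaf <- q_source(ea); Qbf <- q_source(eb)
  wa <- ea$g^constants$L; wb <- eb$g^constants$L
  AM <- (ef$g > ea$g) & (ef$g > eb$g)
  Q_abf <- sum(Qaf * wa + Qbf * wb) / W
  N_abf <- sum(AM * (wa + wb)) / W
  Nm_abf <- sum(AM * ((1 - Qaf) * wa + (1 - Qbf) * wb)) / W
  L_direct <- sum((!AM) * ((1 - Qaf) * wa + (1 - Qbf) * wb)) / W
  list(Q_abf = Q_abf, L_abf = 1 - Q_abf - Nm_abf, N_abf = N_abf,
       Nm_abf = Nm_abf, L_abf_direct = L_direct)
}

#' Full twelve-metric report for a fusion triple
#'
#' Evaluates every quality measure of one `(A, B, F)` triple.
#'
#' @inheritParams fm_cc
#' @param ag_denom passed to [fm_ag()].
#' @return list of class `metric_report` with fields `API`, `SD`, `AG`,
#'   `H`, `MI`, `FS`, `CC`, `SF`, `Q_abf`, `L_abf`, `N_abf`, `Nm_abf`.
#' @export
metric_report <- function(A, B, F, ag_denom = "valid") {
  gp <- gradient_preservation(A, B, F)
  structure(list(
    API = fm_api(F), SD = fm_sd(F), AG = fm_ag(F, ag_denom),
    H = fm_entropy(F), MI = fm_mi_total(A, B, F), FS = fm_fs(A, B, F),
    CC = fm_cc(A, B, F), SF = fm_sf(F),
    Q_abf = gp$Q_abf, L_abf = gp$L_abf, N_abf = gp$N_abf,
    Nm_abf = gp$Nm_abf), class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat("<metric_report>\n")
  for (nm in names(x)) cat(sprintf("  %-6s %.4f\n", nm, x[[nm]]))
  invisible(x)
}

#' Serialize a metric report
#'
#' @param report a `metric_report`.
#' @param path output path.
#' @param format `"json"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_metric_report <- function(report, path, format = c("json", "csv")) {
  format <- match.arg(format)
  if (!inherits(report, "metric_report")) {
    stop_validation("report must be a metric_report")
  }
  if (format == "json") {
    jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                         digits = NA)
  } else {
    df <- data.frame(metric = names(report),
                     value = unlist(report, use.names = FALSE))
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}
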