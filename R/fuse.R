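#' Full pipeline configuration
#'
#' Aggregates every tunable of the fusion pipeline with its default:
#' Wiener `lambda = 0.01`, radius 3; swift `lambda_tune = 3`,
#' `gamma = 1`; salience window 7 with the published gradient form;
#' normalized convolution `sigma_s = 30`, `sigma_r = 0.25`, `T = 3`.
#'
#' @param wiener a [wiener_params].
#' @param swift a [swift_params].
#' @param sse_window odd mean-filter side for salience extraction.
#' @param sse_gradient_mode `"paper"` or `"l1"`, see
#'   [gradient_magnitude()].
#' @param sse_use_swift if `TRUE` (default) salience is extracted from the
#'   swift-enhanced images; if `FALSE`, directly from the Wiener output.
#' @param nc an [nc_params].
#' @param use_enhanced_sources if `TRUE`, the weighted sum combines the
#'   enhanced (processed) images instead of the original intensities.
#' @param guidance `"A"` (default: normalized source A guides the
#'   normalized convolution) or `"mean"` (mean of both normalized
#'   sources, for symmetry-sensitive use).
#' @param output_range `"raw8"` or `"unit"` for the fused image.
#' @return a validated list of class `fusion_config`.
#' @export
fusion_config <- function(wiener = wiener_params(),
                          swift = swift_params(),
                          sse_window = 7L,
                          sse_gradient_mode = c("paper", "l1"),
                          sse_use_swift = TRUE,
                          nc = nc_params(),
                          use_enhanced_sources = FALSE,
                          guidance = c("A", "mean"),
                          output_range = c("raw8", "unit")) {
  sse_gradient_mode <- match.arg(sse_gradient_mode)
  guidance <- match.arg(guidance)
  output_range <- match.arg(output_range)
  if (!inherits(wiener, "wiener_params")) {
    wiener <- do.call(wiener_params, as.list(wiener))
  }
  if (!inherits(swift, "swift_params")) {
    swift <- do.call(swift_params, as.list(swift))
  }
  if (!inherits(nc, "nc_params")) nc <- do.call(nc_params, as.list(nc))
  sse_window <- as.integer(sse_window)
  if (is.na(sse_window) || sse_window < 1L || sse_window %% 2L == 0L) {
    stop_validation("sse_window must be an odd integer >= 1")
  }
  if (!isTRUE(sse_use_swift) && !isFALSE(sse_use_swift)) {
    stop_validation("sse_use_swift must be TRUE or FALSE")
  }
  if (!isTRUE(use_enhanced_sources) && !isFALSE(use_enhanced_sources)) {
    stop_validation("use_enhanced_sources must be TRUE or FALSE")
  }
  structure(list(wiener = wiener, swift = swift, sse_window = sse_window,
                 sse_gradient_mode = sse_gradient_mode,
                 sse_use_swift = sse_use_swift, nc = nc,
                 use_enhanced_sources = use_enhanced_sources,
                 guidance = guidance, output_range = output_range),
            class = "fusion_config")
}

#' @export
print.fusion_config <- function(x, ...) {
  cat("<fusion_config>\n")
  cat(sprintf("  wiener: radius %d, lambda %g\n",
              x$wiener$radius, x$wiener$lam))
  cat(sprintf("  swift:  lambda_tune %d, gamma %g, mode %s (%s)\n",
              x$swift$lambda_tune, x$swift$gamma, x$swift$parse_mode,
              if (x$sse_use_swift) "feeds salience" else "bypassed"))
  cat(sprintf("  sse:    window %d, gradient %s\n",
              x$sse_window, x$sse_gradient_mode))
  cat(sprintf("  nc:     sigma_s %g, sigma_r %g, iterations %d\n",
              x$nc$sigma_s, x$nc$sigma_r, x$nc$iterations))
  cat(sprintf("  fuse:   sources %s, guidance %s, output %s\n",
              if (x$use_enhanced_sources) "enhanced" else "original",
              x$guidance, x$output_range))
  invisible(x)
}

#' Weighted-sum fusion rule
#'
#' `F = W * S_A + (1 - W) * S_B` pixel-wise: a per-pixel convex
#' combination, so the fused value always lies between the two source
#' values and identical sources reproduce themselves exactly.
#'
#' @param I_T weight-map matrix in \[0, 1\].
#' @param S_A,S_B [gray_image]s with matching shape and range tag.
#' @return the fused [gray_image] (same range tag as the sources).
#' @export
weighted_fusion <- function(I_T, S_A, S_B) {
  w <- as_pixels(I_T, arg = "I_T")
  if (min(w) < 0 || max(w) > 1) {
    stop_validation("weights must lie in [0, 1], got [%g, %g]",
                    min(w), max(w))
  }
  if (!is_gray_image(S_A) || !is_gray_image(S_B)) {
    stop_validation("S_A and S_B must be gray_images")
  }
  if (S_A$range != S_B$range) {
    stop_validation("sources have different range tags: '%s' vs '%s'",
                    S_A$range, S_B$range)
  }
  check_same_shape(S_A, S_B)
  check_same_shape(w, S_A$pixels, "weight map and images")
  gray_image(w * S_A$pixels + (1 - w) * S_B$pixels, S_A$range)
}

#' Run the full fusion pipeline
#'
#' Orchestrates all stages on a pre-registered raw8 pair: normalization,
#' adaptive local Wiener filtering, swift contrast enhancement
#' (optionally bypassed for salience), salient structure extraction,
#' normalized-convolution smoothing of the binary salience map with the
#' normalized source A as guidance, and the weighted-sum combination of
#' the *original* intensities (by default). Fully deterministic.
#'
#' @param S_A,S_B co-registered raw8 [gray_image]s of identical shape
#'   (conventionally A = CT, B = MRI).
#' @param config a [fusion_config].
#' @return list of class `fusion_result`: `fused` ([gray_image]),
#'   `weight_map` (matrix in \[0, 1\]), `decision`
#'   (the `decision_result`), and `intermediates` (normalized, Wiener-
#'   filtered and swift-enhanced images per source).
#' @examples
#' pair <- generate_phantom_pair(phantom_spec(size = c(64, 64), seed = 3))
#' res <- fuse_pipeline(pair$ct, pair$mri)
#' res$fused
#' @export
fuse_pipeline <- function(S_A, S_B, config = fusion_config()) {
  if (!inherits(config, "fusion_config")) {
    stop_validation("config must be a fusion_config")
  }
  if (!is_gray_image(S_A) || !is_gray_image(S_B)) {
    stop_validation("sources must be gray_images")
  }
  if (S_A$range != "raw8" || S_B$range != "raw8") {
    stop_validation("sources must be raw8 images")
  }
  check_same_shape(S_A, S_B)

  G_A <- normalize_image(S_A)
  G_B <- normalize_image(S_B)
  W_A <- wiener_filter(G_A, config$wiener)
  W_B <- wiener_filter(G_B, config$wiener)
  sw_A <- swift_enhance(W_A, config$swift)
  sw_B <- swift_enhance(W_B, config$swift)
  t_A <- if (config$sse_use_swift) sw_A$image else W_A
  t_B <- if (config$sse_use_swift) sw_B$image else W_B
  dec <- extract_salient_structure(t_A, t_B, config$sse_window,
                                   config$sse_gradient_mode)
  guide <- if (config$guidance == "A") G_A else {
    gray_image((G_A$pixels + G_B$pixels) / 2, "unit")
  }
  I_T <- nc_smooth(dec$I_A, guide, config$nc)
  I_T <- pmin(pmax(I_T, 0), 1)
  src_A <- if (config$use_enhanced_sources) {
    gray_image(sw_A$image$pixels * 255, "raw8")
  } else S_A
  src_B <- if (config$use_enhanced_sources) {
    gray_image(sw_B$image$pixels * 255, "raw8")
  } else S_B
  fused <- weighted_fusion(I_T, src_A, src_B)
  if (config$output_range == "unit") {
    fused <- gray_image(fused$pixels / 255, "unit")
  }
  structure(list(fused = fused, weight_map = I_T, decision = dec,
                 intermediates = list(
                   G_A = G_A, G_B = G_B,
                   wiener_A = W_A, wiener_B = W_B,
                   swift_A = sw_A$image, swift_B = sw_B$image),
                 config = config),
            class = "fusion_result")
}

#' @export
print.fusion_result <- function(x, ...) {
  cat(sprintf(
    "<fusion_result %dx%d, weights [%.3f, %.3f], A share %.1f%%>\n",
    nrow(x$fused$pixels), ncol(x$fused$pixels),
    min(x$weight_map), max(x$weight_map), 100 * mean(x$weight_map)))
  invisible(x)
}
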