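#' Specification of a synthetic CT/MRI phantom pair
#'
#' Describes a co-registered pair of brain-slice-like test images: a
#' CT-like image (bright elliptical skull ring, near-flat soft tissue)
#' and an MRI-like image of the same scene (dark bone, textured soft
#' tissue). The pair emulates the modality complementarity that
#' gradient-comparison fusion exploits, so the whole pipeline can be
#' exercised without clinical data.
#'
#' @param size integer vector `c(rows, cols)`, each >= 32; default
#'   256x256, the resolution typical of registered CT/MRI slice pairs.
#' @param seed integer; the pair is a pure function of the spec, so equal
#'   specs yield identical pairs.
#' @param noise_sigma additive Gaussian noise std on the unit scale
#'   (applied as `noise_sigma * 255` to the 8-bit images); >= 0.
#' @param bone_intensity skull-ring intensity of the CT-like image on the
#'   unit scale, in (0, 1].
#' @param tissue_contrast amplitude of the MRI soft-tissue texture, in
#'   (0, 1].
#' @return an object of class `phantom_spec`.
#' @seealso [generate_phantom_pair()]
#' @export
phantom_spec <- function(size = c(256L, 256L), seed = 1L,
                         noise_sigma = 0.02, bone_intensity = 0.9,
                         tissue_contrast = 0.5) {
  size <- as.integer(size)
  if (length(size) != 2L || any(is.na(size)) || any(size < 32L)) {
    stop_validation("size must be two integers >= 32")
  }
  if (!is_scalar_num(seed)) stop_validation("seed must be a single number")
  if (!is_scalar_num(noise_sigma) || noise_sigma < 0) {
    stop_validation("noise_sigma must be >= 0")
  }
  for (nm in c("bone_intensity", "tissue_contrast")) {
    v <- get(nm)
    if (!is_scalar_num(v) || v <= 0 || v > 1) {
      stop_validation("%s must lie in (0, 1]", nm)
    }
  }
  structure(list(size = size, seed = as.integer(seed),
                 noise_sigma = noise_sigma,
                 bone_intensity = bone_intensity,
                 tissue_contrast = tissue_contrast),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(
    "<phantom_spec %dx%d, seed %d, noise %.3g, bone %.2f, contrast %.2f>\n",
    x$size[1], x$size[2], x$seed, x$noise_sigma, x$bone_intensity,
    x$tissue_contrast))
  invisible(x)
}

# Elliptical masks shared by both modalities. Axes are fractions of the
# canvas so any size >= 32 scales sensibly.
phantom_masks <- function(m, n) {
  y <- (seq_len(m) - (m + 1) / 2) / (m / 2)
  x <- (seq_len(n) - (n + 1) / 2) / (n / 2)
  yy <- matrix(y, m, n); xx <- matrix(x, m, n, byrow = TRUE)
  inside <- function(ay, ax) (yy / ay)^2 + (xx / ax)^2 <= 1
  outer <- inside(0.84, 0.76)
  inner <- inside(0.72, 0.64)
  list(ring = outer & !inner, interior = inner, outside = !outer)
}

#' Generate a co-registered synthetic CT-like / MRI-like pair
#'
#' The CT-like image has a high-intensity skull ring at
#' `bone_intensity * 255` over a flat soft-tissue interior; the MRI-like
#' image darkens the ring and fills the interior with band-limited random
#' texture (white noise smoothed by a 4 px Gaussian, standardized, scaled
#' by `tissue_contrast`), so salience extraction finds genuine structure
#' in both modalities. Both images receive additive Gaussian noise of std
#' `noise_sigma * 255` and are clipped to \[0, 255\].
#'
#' @param spec a [phantom_spec].
#' @return list with elements `ct` and `mri`, both raw8 [gray_image]s.
#' @examples
#' pair <- generate_phantom_pair(phantom_spec(size = c(64, 64), seed = 7))
#' mean(as.matrix(pair$ct)) > mean(as.matrix(pair$mri))
#' @export
generate_phantom_pair <- function(spec) {
  if (!inherits(spec, "phantom_spec")) {
    stop_validation("spec must be a phantom_spec")
  }
  m <- spec$size[1L]; n <- spec$size[2L]
  msk <- phantom_masks(m, n)
  with_seed(spec$seed, {
    ct <- matrix(0.02, m, n)
    ct[msk$interior] <- 0.35
    ct[msk$ring] <- spec$bone_intensity
    mri <- matrix(0.02, m, n)
    mri[msk$ring] <- 0.08
    tex <- gaussian_blur(matrix(stats::rnorm(m * n), m, n), sigma = 4)
    tex <- (tex - mean(tex)) / stats::sd(tex)
    mri_int <- 0.45 + 0.15 * spec$tissue_contrast * tex
    mri[msk$interior] <- mri_int[msk$interior]
    clip01 <- function(x) pmin(pmax(x, 0), 1)
    ct <- clip01(ct) * 255
    mri <- clip01(mri) * 255
    if (spec$noise_sigma > 0) {
      s <- spec$noise_sigma * 255
      ct <- ct + matrix(stats::rnorm(m * n, sd = s), m, n)
      mri <- mri + matrix(stats::rnorm(m * n, sd = s), m, n)
    }
    clip255 <- function(x) pmin(pmax(x, 0), 255)
    list(ct = gray_image(clip255(ct), "raw8"),
         mri = gray_image(clip255(mri), "raw8"))
  })
}

#' Add Gaussian noise to an image
#'
#' Adds i.i.d. `N(0, sigma^2)` noise on the image's own scale (raw8:
#' intensity units in \[0, 255\]; unit: \[0, 1\]) and clips back to the
#' declared range. Deterministic for a given seed; the caller's RNG
#' state is untouched.
#'
#' @param img a [gray_image].
#' @param sigma noise standard deviation, >= 0.
#' @param seed integer seed.
#' @return a noisy [gray_image] with the same range tag.
#' @export
add_noise <- function(img, sigma, seed = 1L) {
  if (!is_gray_image(img)) stop_validation("img must be a gray_image")
  if (!is_scalar_num(sigma) || sigma < 0) {
    stop_validation("sigma must be >= 0, got %s", format(sigma))
  }
  if (sigma == 0) return(img)
  hi <- if (img$range == "raw8") 255 else 1
  noisy <- with_seed(seed, {
    img$pixels + matrix(stats::rnorm(length(img$pixels), sd = sigma),
                        nrow(img$pixels), ncol(img$pixels))
  })
  gray_image(pmin(pmax(noisy, 0), hi), img$range)
}
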