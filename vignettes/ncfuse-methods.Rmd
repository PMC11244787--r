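---
title: "Methods: salient-structure fusion with normalized convolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: salient-structure fusion with normalized convolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ncfuse)
```

## The problem

CT and MRI image the same anatomy with complementary sensitivity: CT renders
bone (the skull) brightly but shows little soft-tissue contrast, while MRI
resolves soft tissue and renders bone dark. Given a *pre-registered*,
same-size pair of 8-bit slices, pixel-level fusion produces a single image
that keeps the locally most informative source at every pixel. `ncfuse`
implements one such pipeline: the decision of "which source is more
informative here" is made by comparing local gradient magnitudes, and the
resulting binary decision is turned into a smooth, edge-respecting weight
map by normalized convolution over a domain transform.

Registration is assumed, not performed; color fusion and more than two
sources are out of scope.

## The pipeline

For sources $S^A, S^B \in [0,255]^{m\times n}$:

1. **Normalization.** $G = S/255 \in [0,1]$.
2. **Adaptive local Wiener filter.** With local window mean $\mu_w$ and
   population variance $\sigma^2_w$ over a $(2r{+}1)^2$ window,
   $$\bar G = \mu_w + k\,(G - \mu_w), \qquad
     k = \frac{\sigma^2_w}{\sigma^2_w + \lambda}.$$
   $k \in [0,1]$ interpolates between the local mean (flat, noisy patches,
   $\sigma^2_w \ll \lambda$) and the raw pixel (edges,
   $\sigma^2_w \gg \lambda$). Defaults $r = 3$, $\lambda = 0.01$; the
   window radius 7 used in ablation-style experiments is available by
   configuration.
3. **Swift contrast adjustment.** $u = \ln(1+\bar G)$ compresses excessive
   intensities onto $[0, \ln 2]$; the corrected sample standard deviation
   $\varsigma$ of $u$ and the factor $\eta = u^\lambda/\lambda!$
   (integer $\lambda_{\text{tune}} = 3$) feed a nonlinear tone map,
   after which a min–max rescale restores the unit dynamic range.
4. **Salient structure extraction (SSE).** Forward-difference gradients
   give magnitudes $M^A, M^B$; the signed map $D = M^A - M^B$ is averaged
   over a square window (default $7\times7$) and binarized by the strict
   step $I^A = [\,\bar D > 0\,]$.
5. **Normalized convolution (NC).** $I^A$ is smoothed edge-aware: each
   scan line of the guidance image $G^A$ is rewarped by the domain
   transform $ct(x) = \sum_{k \le x} (1 + \tfrac{\sigma_s}{\sigma_r}
   |g(k)-g(k-1)|)$ and box-filtered in the warped coordinate with
   per-sample renormalization $K_p$; iterating $T = 3$ times over rows and
   columns with the variance-preserving radius schedule approximates an
   edge-aware Gaussian. The result $I^T \in [0,1]$ is the weight map.
6. **Weighted-sum fusion.** $F = I^T S^A + (1 - I^T) S^B$ on the original
   intensities — a pixel-wise convex combination, so
   $\min(S^A,S^B) \le F \le \max(S^A,S^B)$ and $F(S,S) = S$ exactly.

## Tunable parameters

| key | default | meaning |
|---|---|---|
| `wiener.radius` | 3 px | Wiener window half-width |
| `wiener.lambda` | 0.01 | regularization; larger smooths harder |
| `swift.lambda_tune` | 3 | integer exponent of $\eta = u^\lambda/\lambda!$ |
| `swift.gamma` | 1.0 | enhancement attenuation ($\Gamma \to \infty$: none) |
| `sse.window` | 7 px | decision-map mean-filter side |
| `nc.sigma_s` | 30 px | spatial scale of the weight-map smoothing |
| `nc.sigma_r` | 0.25 | range scale; `Inf` disables edge awareness |
| `nc.iterations` | 3 | box-filter iterations |

$\Gamma$ has no published value; 1.0 (neutral) is the package default.
$\sigma_s = 30$ px and $\sigma_r = 0.25$ are likewise package choices:
$\sigma_s$ of the order of a tenth of the 256-px canvas diffuses weights
across anatomical regions, while $\sigma_r = 0.25$ (a quarter of the unit
intensity range) lets strong bone/tissue boundaries block the diffusion.

## Design choices where the design was open

* **Tone-map grouping.** The published layout of the swift tone-mapping
  expression is typographically ambiguous. Both readings are implemented
  (`swift.parse_mode`): the default `"fraction"`
  $f = \exp\!\big((\tan u - \varsigma)\,/\,(\Gamma(e^u - \eta))\big)$
  mirrors the gain-flattening pattern of the Wiener step and reproduces
  the documented behaviour of $\Gamma$ (larger $\Gamma$, flatter output);
  `"literal"` is the character-faithful
  $\exp(\tan u - \varsigma e^u - \eta)^\Gamma$. The subsequent min–max
  rescale makes the two nearly monotone-equivalent. For
  $u \in [0, \ln 2]$ and $\lambda_{\text{tune}} = 3$ the fraction
  denominator satisfies $e^u - u^3/6 > 0.9$, so no singularity exists on
  the reachable domain (asserted over a dense grid in the tests).
* **Gradient form.** The printed magnitude $|\partial_x t - \partial_y t|$
  vanishes on exact 45° diagonal ramps; it remains the default
  (`sse.gradient_mode = "paper"`) for fidelity, with the conventional
  $|\partial_x t| + |\partial_y t|$ available as `"l1"`.
* **Ties.** $\bar D = 0$ maps to 0 — source B wins exact ties — by strict
  reading of "positive".
* **Stage order.** The enhanced images feed SSE by default
  (`sse.use_swift = TRUE`); setting it to `FALSE` feeds the Wiener output
  directly, supporting the alternative reading of the flowchart.
* **Box radius.** The per-iteration box radius is $\sqrt 3\,\sigma_{Hi}$,
  matching the variance of the Gaussian it replaces; the schedule
  $\sigma_{Hi} = \sigma_s \sqrt 3\, 2^{T-i}/\sqrt{4^T - 1}$ satisfies
  $\sum_i \sigma_{Hi}^2 = \sigma_s^2$. With $\sigma_r = \infty$ and
  $T = 3$ the iterated filter matches direct Gaussian smoothing to
  PSNR ≥ 40 dB (an acceptance test), which is also the evidence for the
  $\sqrt 3\sigma$ reading of the radius.
* **Wiener gain at $\lambda = 0$.** $k \equiv 1$ is short-circuited to an
  exact pass-through so the filter is bit-transparent when disabled; the
  $0/0$ case (constant window, $\lambda = 0$) takes $k = 0$, which is
  exact there too.
* **Complementarity.** The information-loss measure $L^{AB/F}$ is defined
  by the identity $L = 1 - Q - N_m$, so the reported triple is
  complementary by construction; the independent restricted sum over
  non-artifact pixels is exposed as a diagnostic (`L_abf_direct`) and is
  the quantity used in the acceptance checks, where its agreement with
  the identity is a computed fact.
* **Q-sigmoid constants.** The gradient-preservation sigmoids use the
  standard constants of the objective fusion-metric literature
  ($\Gamma_g = 0.9994$, $\kappa_g = -15$, $\sigma_g = 0.5$,
  $\Gamma_\alpha = 0.9879$, $\kappa_\alpha = -22$, $\sigma_\alpha = 0.8$,
  $L = 1$), exposed via `qabf_constants()`.
* **Average gradient normalization.** `fm_ag()` averages over the
  $(m-1)(n-1)$ pixels that possess both forward differences (a unit ramp
  scores exactly 1); `denom = "mn"` reproduces the full-count variant
  some formulations print.

## The synthetic phantom

`generate_phantom_pair()` emulates only the features the method exploits:
a bright elliptical "skull" ring over a flat interior for CT, a dark ring
with band-limited random soft-tissue texture (white noise blurred by a
4 px Gaussian, standardized, scaled by `tissue_contrast`) for MRI, plus
additive Gaussian noise (default std 0.02 of the intensity range — a
mild, realistic acquisition-noise level; the noise model of real scanners
is not characterized here, so Gaussian is an explicit assumption).
Everything is a pure function of the `phantom_spec`, so tests are exactly
reproducible.

What the phantom does *not* model: anatomy-scale structure diversity,
partial-volume effects, registration error, intensity nonuniformity
(bias fields), Rician MRI noise. A green test on phantoms therefore
establishes the *algorithmic contracts* (determinism, convexity bounds,
oracle agreement, edge-aware behaviour), not clinical image quality.

## Numerical notes

* Local statistics and mean filters use summed-area tables with
  edge-replicate padding; tiny negative variances from cancellation are
  clamped to 0.
* The NC line filter exists twice: a literal two-pointer O(N) sweep and a
  vectorized `findInterval`/`cumsum` equivalent used by the 2-D smoother;
  both are tested against an $O(N^2)$ direct evaluation.
* `nc_smooth()` clamps its output to the input's range: each pass is a
  convex average, so the bounds hold analytically and only ~1e-15
  round-off is removed.
* Degenerate inputs are contracts, not surprises: constant images have
  zero adjustment factor and tone-map to mid-gray 0.5; an all-flat metric
  triple yields vacuous preservation ($Q = 1$) with a warning; zero
  variance makes the correlation coefficient a validation error.
* Quantization to disk is round-half-up (`floor(x + 0.5)`), so a constant
  0.5 unit image writes as 128.

## Limitations

* Fusion quality claims beyond the self-contained properties above
  (e.g. benchmark scores on clinical atlases against competing methods)
  require external data and are deliberately not reproduced.
* The PNG codec reads the common non-interlaced 8/16-bit layouts
  (gray, gray+alpha, RGB, RGBA) and the TIFF codec only uncompressed
  baseline files; palette PNGs and compressed TIFFs are rejected with a
  clear error.
* Runtime is adequate for slice-sized images (a 256×256 fusion takes
  well under a second); no compiled code is used.
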