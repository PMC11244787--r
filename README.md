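# ncfuse

Pixel-level fusion of pre-registered grayscale medical image pairs —
typically a CT slice (bone-bright) and the matching MRI slice
(soft-tissue-rich) — for radiologists' workflows and image-analysis
pipelines that want one image carrying the salient content of both
modalities.

## Method

For 8-bit sources $S^A, S^B$ the pipeline computes

1. $G = S/255$ (normalization);
2. an adaptive local Wiener filter
   $\bar G = \mu_w + k(G-\mu_w)$, $k = \sigma_w^2/(\sigma_w^2+\lambda)$
   (defaults $r=3$, $\lambda=0.01$) — noise smoothed in flat patches,
   edges passed through;
3. "swift" contrast adjustment: $u=\ln(1+\bar G)$, adjustment factors
   $\varsigma$ (sample std of $u$) and $\eta = u^{\lambda}/\lambda!$
   ($\lambda_{\text{tune}}=3$), a nonlinear tone map, and min–max
   restoration of the dynamic range;
4. salient structure extraction: gradient magnitudes $M^A, M^B$,
   decision map $D = M^A - M^B$, $7\times7$ mean filter, strict
   binarization $I^A = [\bar D > 0]$;
5. normalized convolution of $I^A$ guided by $G^A$: per scan line the
   domain transform
   $ct(x)=\sum_{k\le x}\big(1+\tfrac{\sigma_s}{\sigma_r}|g(k)-g(k-1)|\big)$
   turns edge-aware filtering into O(N) box filtering; $T=3$ iterations
   with the variance-preserving radius schedule yield the weight map
   $I^T \in [0,1]$;
6. the weighted-sum rule $F = I^T S^A + (1-I^T) S^B$.

Twelve fusion-quality metrics are included: API, SD, AG, H (entropy),
MI, FS, CC, SF and the gradient-based $Q^{AB/F}$, $L^{AB/F}$,
$N^{AB/F}$, $N_m^{AB/F}$ family, whose transfer/loss/revised-artifact
triple satisfies $Q + L + N_m = 1$.

A synthetic CT/MRI phantom generator (elliptical skull ring, textured
soft tissue) makes the entire package testable without clinical data,
and self-contained grayscale PNG/TIFF codecs remove any image-library
dependency.

## Worked example

```r
library(ncfuse)
pair <- generate_phantom_pair(phantom_spec(seed = 7))   # 256x256 pair
res  <- fuse_pipeline(pair$ct, pair$mri)                # default config
print(res)
metric_report(pair$ct, pair$mri, res$fused)
```

prints

```
<fusion_result 256x256, weights [0.000, 0.634], A share 14.6%>
<metric_report>
  API    56.2150
  SD     52.8272
  AG     9.1289
  H      6.1251
  MI     5.2702
  FS     1.7380
  CC     0.7899
  SF     14.5379
  Q_abf  0.3786
  L_abf  0.6068
  N_abf  0.0345
  Nm_abf 0.0146
```

The weight map gives the CT source a 14.6 % average share — it wins only
near the skull ring, where its gradients dominate, while the textured
MRI interior wins elsewhere. `H` ≈ 6.1 bits and `SD` ≈ 53 show the fused
image keeps a wide, informative intensity distribution; `CC` ≈ 0.79
quantifies its correlation with the sources; and the complementary
triple satisfies `Q_abf + L_abf + Nm_abf = 1` to machine precision.
`write_image(res$fused, "fused.png")` saves the result.

## Command line

```sh
Rscript inst/cli/ncfuse.R phantom --size 256 --seed 7 --noise 0.02 \
        --out-ct ct.png --out-mri mri.png
Rscript inst/cli/ncfuse.R fuse --a ct.png --b mri.png --out fused.png \
        --report report.json
Rscript inst/cli/ncfuse.R metrics --a ct.png --b mri.png --f fused.png
Rscript inst/cli/ncfuse.R sweep --a ct.png --b mri.png \
        --parameter wiener.lambda --values 0,0.01,0.1 --out sweep.csv
```

Configuration files are plain `key = value` text (keys like
`wiener.lambda`, `nc.sigma_s`; see `?load_config`); absent keys keep the
defaults above.

## Documentation

`vignettes/ncfuse-methods.Rmd` describes the model, its assumptions, the
open design choices taken (tone-map grouping, gradient form, tie
handling, box-radius reading) and what the phantom-based tests do and do
not establish.
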