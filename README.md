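# lumenseg

Shape-prior level-set segmentation of the carotid-artery lumen in
longitudinal B-mode ultrasound images.

The blood-filled lumen appears in a longitudinal carotid scan as a dark
band between two bright wall echoes. Speckle, low contrast, slowly varying
gain and missing wall segments defeat purely image-driven active contours,
so `lumenseg` constrains a distance-regularized level-set evolution
(DRLSE) with an anatomically generated shape prior: a band obtained by
extending the vessel's estimated centerline up and down by the narrowest
wall-to-wall half-distance. The model minimizes

    E(phi) = mu*Rp(phi) + lam*Lg(phi) + alpha*Ag(phi)
             + beta * sum( (H_eps(phi) - H_eps(phi0))^2 )

where `Rp` is the double-well distance-regularization energy, `Lg` the
edge-weighted contour length, `Ag` the edge-weighted area (balloon term),
and `phi0` is the signed distance of the prior band. With `beta = 0` the
model is exactly DRLSE; a Chan-Vese baseline is included for comparison.
The prior, the initial contour, and all preprocessing are derived fully
automatically from the image (Otsu threshold, largest connected component,
morphology, centerline); no manual interaction is needed.

The package also ships a synthetic speckle phantom generator with exact
ground truth (clinical carotid datasets are private), the five standard
segmentation metrics (Dice, Hausdorff distance, sensitivity, specificity,
IoU) with cohort aggregation, and a command-line interface.

## Worked example

Generate a moderately degraded phantom, segment it with the shape-prior
model, and score the result:

```r
library(lumenseg)

ph <- phantom_generate(phantom_spec(speckle_looks = 4,
                                    inhomogeneity_amp = 0.2, seed = 1))
init <- auto_initialize(ph$image)   # Otsu -> component -> centerline -> band
res <- proposed_evolve(ph$image, init$phi_init, init$phi0)
res
#> <lumenseg_result: proposed>
#>   iterations: 22 (converged)
#>   mask area : 11280 px
#>   energy    : -2.321e+04 -> -2.393e+04
#>   mean |grad phi| near contour: 1.486
metrics_report(res$mask, ph$truth)
#>     id      dice sensitivity specificity       iou hd
#> 1 <NA> 0.9791667   0.9591837           1 0.9591837  1
```

A Dice of 0.98 against the exact phantom truth and a Hausdorff distance
of 1 px: under 4-look speckle and a 20% gain field the contour lands on
the wall interface to within a pixel. The energy trace is monotone
decreasing, and the mask is the set of pixels with `phi < 0`. The same
pipeline runs from the shell:

```sh
Rscript inst/cli/lumenseg.R phantom --out suite --n 20 --level moderate --seed 1
Rscript inst/cli/lumenseg.R compare --suite suite --out report
Rscript inst/cli/lumenseg.R segment --image suite/img_001.png --out seg
```

`compare` writes a per-image CSV and per-model mean ± SD tables (Dice,
sensitivity, specificity, IoU as percentages; HD in pixels) for the
Chan-Vese, DRLSE and shape-prior models, each started from the same
automatic initialization.

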