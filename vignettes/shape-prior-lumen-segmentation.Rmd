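---
title: "Shape-prior level-set segmentation of the carotid lumen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shape-prior level-set segmentation of the carotid lumen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lumenseg)
```

## The problem

In a longitudinal B-mode ultrasound scan of the carotid artery the lumen
appears as a dark (hypoechoic) band between two bright wall echoes.
Delineating the lumen boundary supports assessment of atherosclerosis and
stroke risk, but B-mode frames are hard material for classical
segmentation: multiplicative speckle, low contrast, slowly varying gain
(grayscale non-uniformity), and stretches of missing wall echo. `lumenseg`
implements a variational segmentation pipeline built around a simple
anatomical observation: at the scale of one frame, the lumen is a
band-shaped region following the vessel's centerline. That band, derived
automatically from a rough segmentation, is used both to initialize an
active contour and to constrain its evolution.

## Models

All models evolve a level-set field $\phi$ on the pixel grid, with the
convention that the segmented region is $\{\phi < 0\}$. The contour is the
zero level set.

**Chan–Vese (baseline).** The piecewise-constant region model with inside
and outside means $c_1, c_2$; energy terms: contour length (weight
`mu_len`), region area (`nu_area`), and the two data terms
$\lambda_i \int (I - c_i)^2$. We use the original arctan Heaviside
$H_\varepsilon(x) = \tfrac12(1 + \tfrac2\pi \arctan(x/\varepsilon))$, whose
Cauchy-kernel derivative has unbounded support, so region competition
reaches every level curve rather than only the contour's neighborhood; the
region means themselves are computed with the compact cosine Heaviside so
that $c_1, c_2$ are effectively hard region averages. The model has no
distance regularizer, so its $\phi$ must be initialized as a signed
distance.

**DRLSE (baseline).** Distance-regularized level-set evolution:

$$\partial_t \phi = \mu\,\mathrm{div}(d_p(|\nabla\phi|)\nabla\phi)
 + \lambda\,\delta_\varepsilon(\phi)\,\mathrm{div}\!\left(g\frac{\nabla\phi}{|\nabla\phi|}\right)
 + \alpha\,g\,\delta_\varepsilon(\phi),$$

with the double-well potential $p(s)$ (minima at $s = 0$ and $s = 1$),
$d_p(s) = p'(s)/s$, the edge indicator
$g = 1/(1 + |\nabla(G_\sigma * I)|^2)$, and the compact cosine
$H_\varepsilon/\delta_\varepsilon$ pair. The regularizer maintains
$|\nabla\phi| \approx 1$ near the contour, so a binary-step initialization
suffices and no re-initialization is ever performed.

**Shape-prior model (the package's main model).** The DRLSE energy plus

$$E_{\mathrm{shape}}(\phi) = \beta \int_\Omega
  (H_\varepsilon(\phi) - H_\varepsilon(\phi_0))^2\,dx,$$

where $\phi_0$ is the signed distance of the prior band. Its descent force
is $-2\beta\,\delta_\varepsilon(\phi)(H_\varepsilon(\phi) -
H_\varepsilon(\phi_0))$: the Dirac factor confines the pull toward the
prior to the contour's narrow band and makes the term a genuine descent
direction of $E_{\mathrm{shape}}$. A `literal_eq14` flag exposes the
unmollified variant $+2\beta(H_\varepsilon(\phi)-H_\varepsilon(\phi_0))$
for comparison; it is not a descent direction and is off by default.

## Automatic prior and initialization

From a raw frame (after an optional ROI crop removing scanner text):

1. **Rough segmentation** — Otsu's threshold on a Gaussian-smoothed copy of
   the frame (`smooth_sigma = 1.5` px); the below-threshold (dark) class is
   kept. The pre-smoothing exists because a global threshold on raw
   speckle assigns a large fraction of dark tissue speckle to the lumen
   class; scanner-processed clinical frames arrive pre-smoothed in this
   sense, synthetic white-speckle frames do not.
2. **Lumen component** — largest 8-connected component of the rough mask.
3. **Wall trace** — morphological closing (disk radius 3), hole filling,
   boundary extraction; kept as a diagnostic artifact.
4. **Initial-contour core** — erosion of the filled lumen by a disk of
   radius 20 px (fallbacks 15/10/5 if fewer than 100 px survive), so the
   initial contour lies strictly inside the lumen and the negative balloon
   weight $\alpha$ unfolds it outward.
5. **Centerline** — per-column midpoint of the longest vertical run of
   lumen pixels, smoothed by a 15-column moving average and clamped back
   into the lumen. A skeletonization alternative was rejected: under
   speckle it branches, while the per-column rule is deterministic, cheap,
   and matched to the near-horizontal geometry of longitudinal scans.
6. **Prior band** — the centerline extended up and down by the narrowest
   wall-to-wall half-distance (minimum per-column run length over the
   central 90% of columns, halved). The band adapts to vessel slope and
   curvature but deliberately *under*-estimates the lumen: it is an anchor,
   not an answer.
7. **Initialization** — the union of the eroded core and the prior band
   (so the initialization always overlaps the prior), clipped 2 px inside
   the image border; $\phi_\mathrm{init}$ is its binary step,
   $\phi_0$ the band's signed distance.

The pipeline contains no randomness: identical frames give identical
initializations.

## Parameters

| Parameter | Default | Meaning |
|---|---|---|
| `dt` | 5 | explicit time step (stability bound `mu*dt < 1/4`) |
| `lam` | 6 | edge-weighted contour-length weight |
| `alpha` | −3.5 | balloon weight; negative expands an inside initialization |
| `beta` | 0.5 | shape-prior weight; 0 reduces the model to DRLSE |
| `mu` | `0.2/dt` | distance-regularization weight, saturating the bound |
| `eps` | 1.5 | Heaviside/Dirac half-width (px) |
| `sigma` | 4 | Gaussian scale of the edge indicator (px) |

`dt`, `lam`, `alpha`, `beta` are the model's reference setting. `mu` and
`eps` follow standard DRLSE practice. `sigma` is the one genuinely open
scale: it must suppress speckle gradients (so that $g$ is not uniformly
tiny and the balloon force can act) while keeping the ~6 px wall echoes
localized. We fixed `sigma = 4` after a one-time grid check on small
development suites: the shape-prior model's accuracy is nearly flat in
`sigma`, whereas the DRLSE baseline degrades sharply for larger values as
blurred walls let the contour leak; picking the middle of the flat region
avoids biasing the baseline comparison either way.

Intensities are used on their native 0–255 scale, so the printed weights
keep their magnitudes relative to the dimensionless $g$. Chan–Vese
defaults (`lam1 = lam2 = 1`, `nu_area = 0`, `mu_len = 0.2·255²`,
`dt = 0.1`) are the conventional choice rescaled to squared-intensity
units.

**Stopping.** All models stop when the symmetric-difference area of
consecutive masks, relative to the current mask, stays below `1e-3` for a
patience window (10 iterations; 30 for Chan–Vese, whose Cauchy Dirac moves
far-field pixels slowly enough that the mask can pause mid-transit), or at
`max_iter` (500; 200 for Chan–Vese). The patience counter only arms once
the mask has changed at least once, because a binary-step initialization
leaves the contour static for the first few iterations while the
regularizer builds a ramp into the Dirac band. If the zero level set
vanishes, the last non-empty mask is returned with `converged = FALSE`.
After the main evolution the edge-based models append a short zero-balloon
tail (`refine_iters = 10`, the conventional count): the balloon force
steepens the interface while it drives the contour, and the tail lets the
distance regularizer settle the field without it.

**Numerical choices.** Unit pixel spacing; replicated-edge (Neumann)
boundary handling for all finite differences and Gaussian convolutions;
$|\nabla\phi|$ floored at `1e-10` before any division; the
distance-regularization term is discretized as
$\mathrm{div}((d_p - 1)\nabla\phi) + \nabla^2\phi$ with a 5-point
Laplacian — the composition of central-difference divergence and gradient
leaves checkerboard modes undamped, and the split form removes them. The
evolving field starts as a binary step of height 6 in the automatic
pipeline: the regularizer rebuilds a slope-1 ramp only up to $|\phi|
\approx c_0$, and a plateau at 6 keeps the far field clear of the
$|\phi| < 3$ near-contour band in which the field is expected to be
distance-like (the generic `binary_step_initial()` default remains the
conventional 2).

## The phantom generator

Clinical carotid data are private; the package ships a synthetic
longitudinal phantom so everything is testable end to end. A phantom is a
dark lumen band (default gray 30) following a sloped/sinusoidal
centerline, 6-px bright walls (200) and mid-gray tissue (110), degraded
by, in order: wall gaps (wall intensity zeroed over given column spans —
echo dropout), a smooth multiplicative inhomogeneity field (bilinearly
upsampled coarse random grid, amplitude `inhomogeneity_amp`), and
per-pixel multiplicative gamma speckle with unit mean and variance
`1/speckle_looks` (the fully-developed-speckle intensity model). Ground
truth is the noiseless lumen band, exact by construction and independent
of the noise draw.

`degradation_suite()` fixes three presets — clean (noise-free, no gaps),
moderate (4-look speckle, inhomogeneity 0.2, one 10-px gap), severe
(1-look speckle, inhomogeneity 0.4, two 15-px gaps) — with randomized
geometry (vertical thickness ~15–41 px, slope up to ±0.3, curvature on or
off), reproducible from a single seed.

What the phantom does *not* emulate matters for interpreting results: the
speckle is spatially white (no point-spread-function correlation, harsher
for gradient-based terms than scanner output), and the scene contains a
single dark band — no jugular vein, plaque, shadowing or annotation
overlays. Consequently the phantom suite is an easier stage for the
Chan–Vese baseline than clinical data are: with exactly one dark
structure, its region competition performs well in Dice terms (while
still fragmenting into many spurious components, visible in its inflated
Hausdorff distances), and the clinical-scale gap between it and the
edge-based models does not reproduce at phantom scale. Likewise, the
automatic initialization lands close to the truth on phantoms, leaving the
baselines less room to fail than the paper-scale clinical comparison
gives them. Passing phantom tests therefore demonstrates correctness of
the machinery and the direction of the ordering, not clinical effect
sizes.

## Evaluation

Five metrics compare a segmentation $X$ with ground truth $G$: Dice,
sensitivity, specificity (TN/(TN+FP) over the image domain — the only
reading of the domain-normalized definition that stays in $[0,1]$), IoU,
and the symmetric Hausdorff distance between *boundary* pixel sets
(region-based HD would be dominated by interior pixels and lose its
meaning as a contour-accuracy measure). Cohorts are aggregated as mean ±
sample SD, fractions reported as percentages, HD in pixels.

Problem sizes used by the test suite and the acceptance script — suites of
10 (clean), 20 (moderate) and 12 (severe) phantoms at 128×192 px — were
chosen as the smallest cohorts at which the suite-level orderings are
stable across seeds.

## Known limitations

- The prior band inherits the *narrowest* wall-to-wall distance, so in
  vessels with strongly varying caliber the prior under-covers wide
  segments; with the default `beta = 0.5` this biases the converged
  contour slightly inward (visible on phantoms as a Dice cost of a point
  or two against plain DRLSE, in exchange for roughly halved Hausdorff
  distances and robustness when edges vanish).
- Transverse (ring-shaped) sections, plaque delineation, and automatic
  text/ROI detection are out of scope; the ROI crop is configuration-driven.
- The Chan–Vese baseline is implemented in its classical global form;
  inhomogeneity-robust variants (local binary fitting and relatives) are
  deliberately not included.
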