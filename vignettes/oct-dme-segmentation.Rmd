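---
title: "Segmenting macular edema in OCT B-scans: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting macular edema in OCT B-scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octdme)
```

## The problem and the model

An OCT B-scan of a retina with diabetic macular edema shows three intensity
populations: a dark vitreous/background, a bright (hyper-reflective)
retinal band, and dark (hypo-reflective) fluid pockets *inside* the band.
The difficulty is that the fluid shares its intensity with the background,
so a single global threshold cannot isolate it: any intensity rule dark
enough to catch the fluid also catches the vitreous. `octdme` resolves this
with two stages.

**Stage 1** clusters pixel intensities with K-means, K = 2. Because the
optimization is one-dimensional, we run Lloyd iteration on the
value-weighted set of unique intensities with deterministic initialization
(minimum and maximum observed intensity), which removes run-to-run
variability and is exact for bimodal histograms; ties in assignment go to
the lower center. The brighter cluster is taken as retina — in OCT the band
is always hyper-reflective relative to the vitreous. Enclosed dark holes
are filled *before* keeping the largest 8-connected component, so fluid
pockets stay inside the region of interest (ROI), and the mean image
intensity over the ROI becomes the retinal reference intensity `C`.

**Stage 2** evolves a level set φ (φ > 0 interior) under a pure balloon
force,

$$\frac{\partial\varphi}{\partial t} = \alpha \,\mathrm{spf}(I)\,|\nabla\varphi|,
\qquad
\mathrm{spf}(I) = \frac{I - (c_1 + c_2)/2}{\max\,|I - (c_1 + c_2)/2|},$$

with a binary Heaviside (φ ≥ 0 counts as interior) for the region means.
The conventional engine re-estimates both `c1` (inside mean) and `c2`
(outside mean) every iteration. The OCT-adapted engine makes two changes:
`c2` is frozen at the Stage-1 reference `C`, and the force is clamped to
the contractive sign outside the retina, so the contour can neither drift
with a moving global background statistic nor leak into the background that
shares the fluid's intensity. Instead of re-initializing φ as a signed
distance function, each iteration maps φ to its ±1 sign and convolves with
a truncated Gaussian — the selective binary + Gaussian regularization that
gives the method its smoothness.

There is no curvature term: the update above is the whole evolution, and
the Gaussian smoothing is the only regularizer. This keeps every iteration
a handful of array operations, which is what makes the method practical on
modest hardware.

## Why the balloon coefficient is negative for the fluid task

With `spf = I - threshold`, a positive α pushes the interior toward pixels
*brighter* than the running threshold `(c1 + c2)/2`; that is the right sign
for segmenting a bright object, and `run_sbgfrls()` defaults to
`alpha = 20`. The DME target is *darker* than the threshold, so the fluid
region is a fixed point of the evolution only when α is negative:
`run_sbgfrls_oct()` defaults to `alpha = -20`, under which the converged
interior is exactly the retina-confined sublevel set
`{I < (c1 + C)/2}`. The ROI confinement clamp respects this: outside the
allowed region the force is set to `-sign(alpha)`, i.e. always the
contractive direction.

## Parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `alpha` | −20 (fluid), +20 (generic) | — | balloon force; sign selects dark/bright target, magnitude the per-step displacement |
| `dt` | 1 | iterations⁻¹ | explicit Euler step; only the product `dt*alpha` matters |
| `sigma` | 1 | px | regularization kernel width; larger = smoother contour, less detail |
| `max_iter` | 2000 | — | hard iteration cap |
| `conv_tol` | 1e−3 | relative | interior-area change counted as stationary |
| `conv_window` | 5 | iterations | consecutive stationary iterations to declare convergence |
| `confine_margin` | 3 | px | erosion of the ROI before force clamping |
| `kmeans_tol` | 1e−8 | intensity | Lloyd stopping tolerance |

`|dt*alpha| = 20` is large relative to the O(1) regularized field: every
pixel where the force and the smoothed sign disagree flips in one step, so
the contour settles onto the signed-pressure zero crossing in a few
iterations, and convergence is governed by the area-stability rule rather
than by slow drift. The convergence comparison is `<= conv_tol` so that a
perfectly stationary contour converges even at `conv_tol = 0`.

`confine_margin` exists because blur and speckle smear the retina/background
transition over roughly `3*blur_sigma` pixels: the innermost pixels of that
transition ring lie inside the K-means retina yet fall below the fluid
threshold `(c1 + C)/2`, and without the margin the contour would crawl
along the retinal border. Eroding the allowed region by 3 px (for the
phantom blur of σ = 1) removes the contaminated ring while leaving any
genuinely internal pocket untouched; the final mask is still intersected
with the full ROI.

**The reference intensity `C`.** Stage 2 needs a single scalar summarizing
the retinal tissue. The package uses the mean image intensity over the
Stage-1 ROI (`c_mode = "roi_mean"`), the only intensity statistic Stage 1
naturally produces for the region the fluid search happens in; the
alternative reading, the mean over the background (`"background_mean"`), is
exposed as a configuration mode so the two can be compared. With the
background mean the threshold `(c1 + C)/2` sits near the fluid intensity
itself and the method degenerates toward the conventional behavior, which
is why `roi_mean` is the default.

## Numerical and degenerate-case choices

* Region means use the binary Heaviside (φ ≥ 0 interior). The selective
  binary step forces φ to ±1 each iteration anyway, so a smoothed Heaviside
  would be indistinguishable; ties (φ = 0) count as interior.
* Within each iteration the order is: region statistics → force → Euler
  step → record area → regularize (feeding the next iteration). The
  reported mask and area trace are sampled *after* the force step: the
  Gaussian smoothing transiently clips isolated high-curvature boundary
  pixels (the σ = 1 kernel center weight is ≈ 0.204, so a lone interior
  pixel smooths to 2·0.204 − 1 < 0) which the following force step
  restores, and sampling after the force step makes the converged mask
  coincide with the threshold set `{I < (c1 + C)/2} ∩ ROI` exactly on
  separable inputs.
* Gaussian kernels are truncated at 4σ (clipped to the grid on tiny
  inputs), normalized, and applied with replicated borders.
* A contour that vanishes in the fluid task is a *result*, not an error: a
  retina without fluid is a valid outcome, returned as an all-false mask
  with `converged = TRUE` and an explanatory note. In the conventional
  engine the same event is an error carrying the iteration index, since
  that engine has no notion of "no object".
* A constant image is rejected at Stage 1 as degenerate clustering; images
  smaller than 8×8 are rejected at load (the stencils need a
  neighborhood).
* Seeding: the fluid contour is initialized on ROI pixels below
  `(c_dark + C)/2` (`c_dark` = darker K-means center). This threshold is
  always below the K-means class boundary `(c_dark + c_bright)/2` because
  `C < c_bright`, so initial seeds never sit on the retina/background
  transition. If no pixel qualifies, a single seed is placed on the
  darkest ROI pixel (first in row-major order on ties) so the interior
  mean is defined; on a fluid-free retina that seed then collapses.

## What the phantom emulates — and what it does not

`generate_phantom()` builds a parabolic hyper-reflective band
(`mu_band = 0.75`) over a dark background (`mu_bg = 0.10`) with ellipsoidal
pockets (`mu_fluid = 0.12`), multiplies by per-pixel gamma speckle with
mean 1 (shape 30 ≈ 18% multiplicative noise, the coherent-imaging noise
model for OCT), blurs with a σ = 1 Gaussian, and clips to [0, 1]. Truth
masks are drawn from the pre-noise geometry, giving an unambiguous
evaluation reference. `default_suite()` randomizes band position, curvature
(4–14 px of sag), thickness (36–48 px) and 0–3 pockets (semi-axes 4–7 ×
8–14 px, placed with 4 px of clearance inside the band) on a 128×192 grid —
sizes chosen so a full 20-phantom suite segments in seconds while keeping
pocket boundaries several kernel widths long.

The phantom deliberately omits retinal layering, vessel shadowing, motion
artifacts, and the low-contrast/high-speckle failure modes that also
challenge clinical reading. Passing the phantom suite therefore
demonstrates the *mechanics* of the method — exact threshold recovery,
confinement, convergence, noise robustness at calibrated speckle — not
clinical performance; agreement statistics on real B-scans must be
established against expert annotation.

## Baseline comparison

On matched tasks (same initialization, same parameters) the fixed-reference
engine reaches area-stable convergence in fewer iterations than the
conventional engine, whose threshold keeps moving as both region means are
re-estimated; the package's acceptance script measures both medians on a
20-phantom suite. The conventional engine is also structurally unable to
confine itself to the retina when fluid and background share intensities —
the motivation for the OCT adaptation.

## Known limitations

* Single 2-D B-scans only; no volumetric (3-D) evolution.
* No preprocessing: heavy speckle or low band/background contrast degrades
  Stage 1, and everything downstream depends on the Stage-1 ROI.
* Pure balloon evolution has no curvature penalty, so in extreme noise the
  contour inherits whatever roughness survives the Gaussian smoothing.
* The pixelwise metrics treat all pixels equally; small pockets contribute
  little to Dice, and no boundary-distance metrics are provided.
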