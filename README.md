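# octdme

Two-stage level set segmentation of diabetic macular edema (DME) in retinal
optical coherence tomography (OCT) B-scans.

DME — fluid accumulating in the macula when the blood–retinal barrier breaks
down — appears on an OCT B-scan as dark (hypo-reflective) pockets inside the
bright retinal band. Delineating those pockets by hand is slow and
subjective; `octdme` implements a fully automatic, training-free pipeline
aimed at exactly that task, for researchers and screening workflows that
need a simple, reproducible fluid delineation plus the usual pixelwise
agreement metrics.

## Method

**Stage 1 — retina extraction.** Intensity K-means with K = 2 (deterministic
1-D Lloyd iteration, centers initialized at the observed minimum and
maximum) splits the B-scan into a bright retinal cluster and a dark
background cluster. Enclosed dark holes (candidate fluid) are filled, the
largest 8-connected component is kept, and the mean intensity of the
resulting region of interest (ROI) becomes the fixed retinal reference
intensity *C*.

**Stage 2 — fluid delineation.** A selective binary and Gaussian filtering
regularized level set (SBGFRLS) evolves a contour φ under the balloon
update

&nbsp;&nbsp;&nbsp;&nbsp;∂φ/∂t = α · spf(I) · |∇φ|,&nbsp;&nbsp;&nbsp;&nbsp;
spf(I) = (I − (c₁ + c₂)/2) / max|I − (c₁ + c₂)/2|,

where c₁ and c₂ are the mean intensities inside and outside the contour.
The OCT-adapted variant (`run_sbgfrls_oct()`) replaces the evolving c₂ with
the *fixed* Stage-1 reference *C*, re-estimates only c₁, confines the force
to the retina, and regularizes by mapping φ to its ±1 sign map and smoothing
it with a truncated Gaussian instead of classical re-initialization. The
conventional engine (`run_sbgfrls()`) is included as a baseline; on matched
phantom tasks the fixed-reference variant converges in fewer iterations.

Evaluation uses pixelwise Dice (2·tp/(2·tp+fp+fn); > 0.70 is conventionally
"excellent agreement"), precision, sensitivity and specificity. Because
clinical B-scans cannot ship with the package, a seeded phantom generator
(`generate_phantom()`, `default_suite()`) emulates the imaging physics: a
curved hyper-reflective band over a dark background, ellipsoidal
hypo-reflective pockets, multiplicative gamma speckle of mean 1, and
Gaussian blur — with ground-truth masks drawn from the pre-noise geometry.

## Worked example

```r
library(octdme)

s <- generate_phantom(phantom_params(
  pockets = list(c(60, 80, 5, 10), c(68, 130, 4, 9)), seed = 11L
))
model <- kmeans_intensity(s$image)
roi   <- extract_roi(s$image, model)
res   <- run_sbgfrls_oct(s$image, roi)
roi; res
#> Retinal ROI: 7684 px (31.3% of frame), C = 0.7158 (roi_mean)
#> Level set segmentation: 261 px interior, 7 iterations, converged
metrics_json(metrics_report(res$mask, s$dme_truth))
#> {"dice":0.9867,"precision":0.9962,"sensitivity":0.9774,
#>  "specificity":0.99996,"tp":260,"fp":1,"tn":24309,"fn":6}
```

The two K-means centers (0.107, 0.734) are the background/fluid and band
intensities recovered from the speckled image; `C = 0.716` is the retinal
reference; the contour converges in 7 iterations to a 261-pixel fluid mask
that overlaps the 266-pixel ground truth at Dice 0.987.

A shell front end is installed with the package
(`system.file("cli", "octdme", package = "octdme")`):

```sh
octdme segment scan.png --alpha -20 --outdir out/   # masks + overlay + JSON report
octdme evaluate out/scan_dme.png truth.png          # metrics JSON on stdout
octdme phantom --n 5 --seed 1 --outdir phantoms/    # seeded phantom suite
```

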