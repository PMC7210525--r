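Package: octdme
Title: Two-Stage Level Set Segmentation of Macular Edema in Retinal OCT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detection and delineation of diabetic macular edema (DME) fluid
    pockets in retinal optical coherence tomography (OCT) B-scans. Stage 1
    partitions the B-scan into retina and background by deterministic
    intensity K-means (K = 2); Stage 2 delineates hypo-reflective fluid
    inside the retina with a selective binary and Gaussian filtering
    regularized level set (SBGFRLS) whose signed pressure force is anchored
    to the fixed Stage-1 retinal reference intensity. Includes the
    conventional SBGFRLS baseline, pixelwise evaluation metrics (Dice,
    precision, sensitivity, specificity), a seeded synthetic speckle phantom
    generator with ground-truth masks, and command-line entry points.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    tiff,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
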