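Package: contraplane
Title: Contralateral Standard-Plane Estimation and Comparison in 3D C-Arm Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-stage pipeline that localizes one or two ankle joints in an
    isotropic 3D cone-beam volume and estimates each joint's three orthogonal
    standard viewing planes by segmenting artificial cylinder masks, recovering
    plane parameters by per-class principal component analysis, and aligning
    the two sides (mirrored to a common laterality) for side-by-side
    multiplanar comparison. Includes a synthetic ankle phantom generator with
    exact ground-truth frames, a small 3D U-Net segmenter with a combined
    cross-entropy and soft-Dice loss, sliding-window patch inference with mean
    fusion, weighted k-means landmark clustering, oblique slice resampling,
    and the evaluation metrics (pos, pos2Ax, per-plane angular deviation).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    yaml,
    png,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
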