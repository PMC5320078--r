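Package: ventriseg
Title: Ventricle Segmentation in Non-Contrast Head CT with Ischemic-Stroke Exclusion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Threshold-based segmentation of the brain ventricular system in
    non-contrast head CT of ischemic-stroke patients. The pipeline strips the
    skull at a fixed 100 HU threshold, detects falx-cerebri light curves with a
    vertical Gaussian filter and a horizontal Laplacian line mask, fits the 3D
    midsagittal plane by least squares and rigidly aligns each slice, estimates
    the ventricular intensity range from a 2-means split and histogram-slope
    tracking, and excludes stroke lesions with three schemes: largest 3D
    connected component, image differencing with a critical-threshold search
    against a brain-edge annulus detector, and an adaptive ventricle template.
    Includes a synthetic head-CT phantom generator with ground-truth masks and
    a full evaluation suite (Dice, sensitivity, specificity, boundary RMSE,
    reliability, volume correlation).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti,
    EBImage
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    yaml
Config/testthat/edition: 3
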