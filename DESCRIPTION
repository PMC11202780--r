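Package: ctsurv
Title: Two-Year Survival Classification from CT Tumor Slice Stacks with
    Penalized Cross-Entropy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for two-year survival classification of lung-cancer
    patients from radiotherapy CT studies. Reads CT series and RTSTRUCT
    structure sets (DICOM Part-10), localizes the primary gross tumor
    volume (GTV-1) by SOP-instance-UID intersection, rasterizes mm
    contours to per-slice binary masks, detects and repairs common
    segmentation defects (area collapses via shape-based inter-slice
    interpolation, bilateral regions via laterality selection), builds
    normalized 5-slice input stacks centred on the largest-tumor-area
    slice, derives the GTV1-SliceNum clinical feature, and trains a 3D
    convolutional classifier with a family of imbalance-aware losses
    including the penalized binary cross-entropy (PEN-BCE) with
    hinge-squared false-negative/false-positive penalties. A synthetic
    cohort generator emits DICOM fixtures so the full pipeline runs
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    randomForest,
    Rcpp,
    rpart,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
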