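Package: bdskseg
Title: Segmentation-Based Classification of Bowen's Disease and Seborrheic
    Keratosis in Whole-Slide Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end computer-aided diagnosis pipeline for H&E-stained skin
    whole-slide images. Separates tissue from background, plans overlapping
    tiles in physical units, segments Bowen's disease (BD) and seborrheic
    keratosis (SK) with a reduced U-Net (ResNet-style encoder, two decoder
    up-sampling levels, stride-8 two-channel probability output) trained by
    focal-loss minimisation, stitches tile heat maps into section heat maps,
    and turns them into section-level diagnostic calls via minimum-area
    thresholds and a relative-area rule. Includes the operating-point
    calibration (minimum-area line search by ROC AUC, probability-threshold
    selection by the F-beta score) and a seeded synthetic slide generator with
    pixel-level ground truth for validation without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    graphics,
    grDevices,
    jsonlite,
    png,
    Rcpp,
    stats,
    tools,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
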