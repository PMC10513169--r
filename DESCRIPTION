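Package: cathtrack
Title: Image-Based Tracking of Gadolinium-Filled Balloon Catheters in
    Real-Time MR Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An automatic, parameter-free pipeline for image-based tracking
    of the gadolinium-filled balloon tip of a wedge catheter in dynamically
    acquired multi-slice magnetic-resonance images. Provides a semi-artificial
    training-data simulator (procedural cardiac-like phantoms with an
    anisotropic 2D Gaussian balloon-signal model and programmatic ground-truth
    masks), a compact residual encoder-decoder segmentation network trained
    with the Dice loss under extreme class imbalance, a multi-slice
    disambiguation step that yields a unique catheter-tip estimate per
    dynamic, and a detection-evaluation scheme based on a center-of-mass
    criterion with per-patient metric aggregation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    withr,
    optparse,
    png,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
LinkingTo:
    Rcpp
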