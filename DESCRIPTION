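Package: foodarea
Title: Image-Based Food Area and Weight Estimation from Capture Geometry
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates the weight of plated food from a single top-view
    photograph. Converts segmented pixel counts to physical area (cm^2)
    using 35-mm-equivalent focal-length geometry derived from the thin-lens
    equation, then maps area to weight with trait-stratified linear
    calibration models (block/thick-bar, slice/silk, grain/granule).
    Includes classical plate-circle and food-edge segmentation, calibration
    model fitting with validation statistics (paired t, Pearson,
    one-sample t), and a synthetic top-view scene generator with exactly
    known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    jsonlite,
    stats,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
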