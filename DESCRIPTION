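Package: limbalign
Title: Automated Lower Limb Alignment Measurement on Full-Leg Radiographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-stage automated measurement of five lower limb alignment
    angles (mMPTA, mLDFA, mFAmTA, mLDTA, FSAmTA) on weight-bearing
    antero-posterior full-leg radiographs: window-based DICOM/PNG
    preprocessing, trainable instance segmentation of femur, tibia, fibula,
    talus and knee implants, side-aware region crops, heatmap-regression
    landmark placement, mechanical-axis goniometry with per-parameter
    detection-rate accounting, and the agreement-statistics battery
    (mean error, SD, RMSE, Pearson r, absolute-agreement single-measure
    ICC with confidence intervals) used to validate such pipelines.
    Includes a synthetic radiograph phantom generator with analytic
    ground truth so every stage is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
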