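Package: copmat
Title: Body Center-of-Pressure Estimation from a Tactile Pressure Mat
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Toolkit for estimating whole-body center of pressure (CoP) from a
    low-cost 64x64 piezoresistive tactile pressure mat, optionally fused with
    lower-limb joint kinematics from a calibrated stereo camera pair. Provides a
    seeded synthetic-cohort simulator (balance protocols, sensor defect models,
    stereo-projected 33-keypoint skeletons, analytic ground-truth CoP), the
    tactile preprocessing chain (module stitching, baseline calibration,
    thresholding, min-max 8-bit quantization, median denoising, drop filling,
    weighted-mean CoP), DLT triangulation and joint-angle kinematics, multi-rate
    stream synchronization onto a 14 Hz reference, encoder-decoder sequence
    regressors (2D CNN or ResNet encoders with LSTM or Bi-LSTM decoders and
    two-stage feature fusion), and a leave-one-subject-out evaluation protocol
    with RMSE/NRMSE/R2 metrics and two-way repeated-measures ANOVA.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    signal,
    jsonlite,
    yaml,
    ggplot2,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
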