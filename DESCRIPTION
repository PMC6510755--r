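Package: mipguard
Title: Patient Misidentification Alerts for Whole-Body PET via
    Demographic Prediction from Maximum Intensity Projections
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Guards against patient misidentification in whole-body
    FDG-PET by predicting demographics directly from the images and
    comparing them with the claimed patient record. Multi-angle
    maximum-intensity-projection (MIP) images are rendered from an SUV
    volume, a small convolutional neural network predicts sex
    (classification) and age or body weight (regression) per image,
    per-image predictions are aggregated to a patient-level decision by
    majority rule, and mismatch alerts are raised against the claimed
    record. Includes region-masking ablation and Grad-CAM attribution
    for model interpretation, and a synthetic whole-body phantom
    generator so the full pipeline trains and evaluates without
    clinical data. The network (four convolutional layers, three
    max-pooling stages, local response normalization, dropout, Adam,
    validation-loss early stopping) is implemented in the package with
    compiled kernels.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    png,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
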