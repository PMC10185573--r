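Package: optodecast
Title: Machine-Learning Calibration and Chemical Imaging for Dual-Analyte
    Luminescent Optodes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Calibration pipeline for hyperspectral images of luminescent
    dual-analyte (pH / dissolved oxygen) optodes. Provides a physics-based
    forward simulator of the coupled sensor spectra (Boltzmann pH sigmoid,
    simplified Stern-Volmer oxygen quenching, reference dye, inner-filter
    cross-talk), ENVI cube and calibration-table input/output, data
    preparation (5x5-pixel region-of-interest tiling, interquartile-range
    outlier cleaning, median aggregation, dataset balancing), a three-layer
    cascaded gradient-boosted regression model (pH, then conditional oxygen,
    then iterative oxygen refinement), model selection across nine regressor
    families, hyperparameter sweeps, k-fold cross-validated MAE/RMSE
    reporting, and pixel-wise conversion of hyperspectral cubes into
    chemical images of pH and oxygen partial pressure.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    withr,
    png,
    xgboost,
    glmnet,
    ranger,
    e1071,
    rpart,
    nnet,
    caret
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
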