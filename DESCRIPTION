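Package: vidradiomics
Title: Video Radiomics for Predicting HER2 Status from Breast Ultrasound
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end video radiomics pipeline for predicting binary
    HER2 expression status from breast ultrasound video. Provides per-frame
    lesion box tracking with outlier rejection and interpolation, 91 static
    radiomics features per frame (first-order, local binary pattern and
    gray-level co-occurrence families), 24 time/frequency-domain features
    per static-feature trajectory (2184 per video), PCA plus a two-branch
    imaging/clinical classifier fusion over SVM, random forest, logistic
    regression and XGBoost base models, and an evaluation layer with
    bootstrap confidence intervals and a paired repeated-resampling model
    comparison. A synthetic speckle-video cohort generator makes every
    stage testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    png,
    EBImage,
    e1071,
    randomForest,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
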