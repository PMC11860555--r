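Package: wearanx
Title: Synthetic Multimodal Wearable Signals and Anxiety-State Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, fully synthetic test bed for feature-based anxiety
    detection from multimodal wearable recordings (ECG, respiration, EDA, BVP,
    skin temperature and accelerometry). Provides generators for cohort-level
    recordings with known anxiety structure, signal conditioning (zero-phase
    Butterworth filtering, Hampel outlier removal, min-max normalisation,
    decimation, mean imputation, SNR-calibrated Gaussian noise injection),
    multiscale (AMPD) R-peak detection with ground-truth scoring, sliding-window
    feature extraction, STAI-based labelling with majority-class undersampling,
    cross-validated training of seven classifier families, squared-importance
    feature aggregation, and a no-fine-tuning transfer-learning harness across
    noise-augmented datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    pracma,
    jsonlite,
    MASS,
    class,
    e1071,
    rpart,
    randomForest,
    xgboost,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    withr
Config/testthat/edition: 3
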