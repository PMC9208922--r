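Package: milcascade
Title: Cascaded-Recalibrated Multiple Instance Learning for Patient-Level
    Lung Cancer Prediction from CT Nodule Patches
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a cascaded-recalibrated multiple instance learning
    (MIL) pipeline for predicting pathologically confirmed, patient-level
    lung cancer from 64x64 grayscale CT nodule patches. Attribute-specific
    convolutional extractors are trained by score regression on radiologist
    semantic attributes (texture, sphericity, malignancy, lobulation,
    spiculation, margin, calcification, subtlety, internal structure) on an
    unlabeled discovery group, then transferred to a diagnosis group where
    softmax recalibration pools attribute features into nodule embeddings
    and nodule embeddings into a patient embedding for bag-level
    classification. Includes instance-space, embedding-space, and
    single-level recalibrated MIL baselines, a three-step training protocol
    with attribute ranking and top-k source selection, stratified
    patient-level cross-validation, evaluation metrics, coefficient-based
    interpretability reports, and a synthetic cohort generator that emulates
    the statistical structure of attribute-scored nodule data so the whole
    pipeline runs on a laptop CPU without any external download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
LinkingTo:
    Rcpp,
    RcppArmadillo
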