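Package: bmradiomics
Title: Radiomic Texture Pipeline for Mutation-Status Prediction from 3D Lesion MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end radiomics benchmark for predicting a binary
    molecular label (EGFR mutation status) from contrast-enhanced
    T1-weighted MRI of brain metastases. Provides a synthetic two-class
    lesion-cohort generator with controllable class-texture differences,
    a preprocessing chain (multiplicative bias correction, cropping,
    z-score normalization), extraction of an ordered 1209-entry feature
    vector per lesion (6 first-order, 25 gray-level co-occurrence and
    run-length texture features, and 38 root-filter-set response maps
    with 31 features each), seven feature-selection algorithms, four
    classifiers evaluated on a cross-validated grid with AUC, and a
    label-permutation significance test.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    ranger,
    e1071,
    glmnet,
    rpart,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
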