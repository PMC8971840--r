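Package: petlung
Title: Automated PET-CT Pulmonary Nodule Localization and Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for differentiating malignant from benign pulmonary nodules
    on co-registered FDG PET-CT volumes. Implements a deterministic,
    annotation-free lung-field localizer (mediastinal-window binarization,
    body-contour selection, central-band air-fraction apex detection, aligned
    3D CT/PET sub-volume extraction), the manual-annotation alternative
    preprocessing, display-window and model-input normalizations, a 3D
    high-resolution multi-branch convolutional classifier with a residual
    baseline trained by stratified k-fold cross-validation, class-activation
    heatmaps, ROC/AUC machinery with DeLong confidence intervals and paired
    AUC comparison, summary-statistic group tests, and a parametric synthetic
    thorax phantom generator so the whole chain is testable without patient
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    EBImage,
    stats,
    utils,
    methods,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
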