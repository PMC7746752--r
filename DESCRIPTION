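Package: coronalAD
Title: Coronal-Slice Convolutional Classification of Alzheimer's Disease
    from Structural MRI
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for classifying Alzheimer's disease versus cognitively
    normal subjects from T1-weighted 3D brain volumes using 2D coronal
    slices over the medial temporal lobe. Implements a synthetic brain
    phantom generator with controllable medial-temporal atrophy, two-step
    rigid template alignment with morphological brain extraction, coronal
    slice extraction with per-slice min-max normalization, stochastic slice
    augmentation, a metadata-augmented convolutional slice classifier
    trained with Nesterov momentum SGD, stratified five-fold
    cross-validation with slice- and fold-ensembled subject prediction, and
    an evaluation layer with ROC/AUC, Youden operating points, DeLong
    comparisons and t-test/chi-square cohort statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti,
    pROC,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
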