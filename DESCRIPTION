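Package: brainpattern
Title: Longitudinal Expression of Multivariate Gray-Matter Patterns
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how the expression of multivariate structural
    brain patterns progresses over time. Trains a disorder-vs-control support
    vector classifier and a brain-age support vector regressor on voxel-based
    gray-matter density maps under repeated nested cross-validation with
    strictly in-fold preprocessing (control-based z-normalization, Gaussian
    smoothing, covariate regression, PCA, min-max scaling), applies the fitted
    ensembles to external cohorts without retraining, and quantifies
    longitudinal change in pattern expression with DeLong ROC comparisons,
    linear mixed models, permutation tests of prognostic AUC, cross-validation
    ratio reliability maps, and voxelwise inference with threshold-free
    cluster enhancement and max-statistic permutation FWE correction. A
    multi-site synthetic-cohort simulator with planted disorder and aging
    patterns provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    e1071,
    lme4,
    lmerTest,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
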