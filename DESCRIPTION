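Package: boldmvpa
Title: Multivoxel Pattern Decoding and Nonparametric Inference for
    Event-Related BOLD Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multivoxel pattern analysis (MVPA) of event-related
    fMRI experiments in which two binary neural codes -- the category of a
    viewed stimulus (face vs scene) and its relevance to the current task
    goal -- are decoded from trial-wise BOLD activity patterns. Provides a
    synthetic cohort generator that plants multivoxel codes into simulated
    BOLD runs with a jittered one-back design, nuisance-GLM preprocessing
    (motion + polynomial drift regression, baseline subtraction, run-wise
    temporal z-scoring, lag-specific trial-pattern extraction),
    L2-regularized logistic-regression ROI decoding and a Gaussian Naive
    Bayes cubic searchlight under leave-one-run-pair-out cross-validation,
    and three tiers of nonparametric inference: within-run permutation
    nulls for above-chance decoding, matched-permutation tests for
    condition differences in decoding accuracy, and bootstrap group
    searchlight inference with empirical cluster-extent correction, plus
    FDR-thresholded functional ROI definition and brain-behavior
    statistics (Spearman rank correlation with exact permutation p,
    median-split Welch t-test).
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
    Rcpp,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
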