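Package: patternsep
Title: Decoding Overlapping Episodic Memories from Multi-Voxel Patterns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tidyverse-native pipeline for multivariate pattern analysis
    (MVPA) of highly overlapping episodic memories in medial-temporal-lobe
    fMRI data. Provides balanced pseudo-random experimental designs for a
    2x2 event-by-context condition structure, a synthetic-data generator
    with separable bound-memory, shared-context and shared-event signal
    components, single-trial beta-series GLM estimation with canonical
    double-gamma HRF regressors and beta-to-t conversion, NIfTI region of
    interest masking and voxel-pattern extraction, four-way linear
    support-vector-machine decoding with leave-one-trial-out
    cross-validation, cross-classification transfer tests of shared spatial
    context and event content, misclassification decomposition into
    spatial, content and orthogonal error types, and group-level inference
    via one-tailed t-tests and label-permutation tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    readr,
    jsonlite,
    RNifti,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    e1071,
    withr
Config/testthat/edition: 3
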