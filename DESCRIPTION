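Package: predictome
Title: Connectome-Based Behavioral Prediction with Multikernel Ridge
    Regression and Haufe Feature Inversion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Predicts behavioral phenotypes from multi-state functional
    connectivity (rest and task fMRI) using correlation-kernel ridge
    regression under site-clustered nested cross-validation. Implements
    motion-based frame censoring and run quality control, Fisher-z run
    averaging of Pearson connectivity matrices, a multikernel framework
    combining brain states, Haufe inversion of fitted models into
    edge-level predictive-feature matrices, network-block summary and
    sign-consistency statistics with within-site permutation nulls,
    corrected resampled t-tests for fold-paired model comparisons, and
    cross-behavior model and feature transfer. A synthetic-cohort
    generator with planted ground truth (domain-structured behaviors,
    shared individual connectivity, motion confounding, site effects)
    supports validation without access-restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
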