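Package: ocboundary
Title: Normality-Boundary Modelling of Brain Activation Patterns with the
    One-Class Support Vector Machine
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Treats patient classification as an outlier-detection problem:
    a nu-one-class support vector machine with a Gaussian (RBF) kernel learns
    the boundary of "normal" brain-activation patterns from healthy-control
    coefficient (beta) images, and scores new subjects by their signed
    distance surrogate to that boundary. Provides voxel- and atlas-region
    feature construction from NIfTI volumes, an in-house sequential-minimal-
    optimisation solver for the one-class dual, nested leave-one-out
    hyperparameter selection with a two-step (kernel width, then nu) search,
    label-permutation significance testing, severity correlation and
    treatment-response tabulation, RBF pre-image weight maps with one-sample
    t-maps for comparison, and a seeded synthetic cohort generator so the
    whole pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    e1071,
    kernlab,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
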