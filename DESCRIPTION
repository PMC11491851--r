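Package: decabt
Title: Decoding Dynamic Attentional-Bias States from Pre-Stimulus fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for studying trial-level attentional-bias states in gaming
    disorder from approach-avoidance task behaviour and pre-stimulus fMRI.
    Provides reaction-time based trial labelling with block-wise neutral
    baselines and split-half reliability, voxel quality control, per-block
    detrending and z-scoring, pre-stimulus feature extraction with a
    hemodynamic shift, sparse Bayesian logistic regression with automatic
    relevance determination and its iterative wrapper (iSLR), leave-one-run-out
    cross-validation with bootstrap class balancing, condition-crossing and
    search-ROI analyses, group statistics with BH-FDR control, a simulator of
    closed-loop decoded attentional-bias training (DecABT), and a synthetic-data
    generator that emulates the block design so the full pipeline is testable
    without scanner data.
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
    purrr,
    Rcpp,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    knitr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
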