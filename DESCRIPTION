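Package: ecogmapr
Title: ECoG-Based Functional Language Mapping with Hybrid Time-Frequency Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies implanted electrocorticography (ECoG) electrodes as
    positive or negative language-response channels from task-based recordings.
    Implements the five-stage pipeline: trimming and uniform block segmentation
    of alternating 30 s control/active task blocks, sliding-window time-domain
    features (moment statistics and Hjorth parameters), autoregressive
    frequency-domain features fitted by Burg reflection-coefficient estimation,
    a family of 1D-convolutional/LSTM fusion networks trained on sub-block
    feature streams, and majority voting to channel labels under channel-grouped
    shuffle-split cross-validation.  Ships a seed-deterministic synthetic ECoG
    cohort generator emulating the story-listening task paradigm for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    e1071,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
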