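Package: plsleep
Title: Post-Learning Sleep, Courtship Memory and Circuit Connectivity Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-style analysis pipeline for Drosophila post-learning
    sleep studies. Scores sleep from video-tracked locomotion (60-s activity
    binning with a displacement threshold, the 5-minute immobility rule,
    30-minute pooling and per-fly delta-versus-control contrasts), estimates
    sleep-depth transition probabilities (P(doze), P(wake)) in sliding windows,
    computes courtship suppression indices with seedable permutation tests,
    background-corrects and normalizes luminescence reporter plate traces,
    analyses stimulus-locked calcium imaging (dF/F, epoch averaging,
    excitatory/inhibitory functional-connectivity calls, spontaneous activity),
    thresholds and aggregates connectome synapse-count edge tables, and
    simulates all five raw-data modalities with known ground truth so every
    stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    generics,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
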