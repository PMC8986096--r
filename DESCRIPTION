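Package: staterep
Title: State Representations in Reinforcement Learning of an Odor-Guided Choice Task
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates an odor-guided two-well choice task with delay and
    magnitude blocks, unsignaled contingency reversals and an adaptive
    delay staircase, and fits Rescorla-Wagner reinforcement-learning models
    that differ only in their state representation (four-state, six-state,
    hybrid-value, hybrid-learning) to trial-by-trial choices. Provides
    per-animal maximum-likelihood and hierarchical Bayesian fitting, WAIC
    model comparison with paired difference standard errors, model-agnostic
    behavioral analyses (block-aligned learning curves and a hierarchical
    logistic regression testing generalization from forced- to free-choice
    trials), and scripted simulation studies for parameter recovery and
    model identifiability.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    lme4,
    jsonlite,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
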