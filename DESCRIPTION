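Package: pavlearn
Title: Reinforcement-Learning Models of Go/No-Go Gain-Loss Learning
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested pipeline for model-based analysis of probabilistic
    go/no-go learning in gain and loss domains. Implements a nested family
    of delta-rule reinforcement-learning models (split learning rates by
    prediction-error sign and valence domain, outcome-impact scaling,
    action bias, Pavlovian stimulus-value coupling), hierarchical type-II
    maximum-likelihood fitting by expectation-maximization with the Laplace
    approximation, integrated-BIC model comparison with stepwise forward
    selection, a synthetic-cohort generator matching the task design
    (block-randomized 4-condition schedules, 80/20 probabilistic feedback),
    and behavioural summary statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    rlang,
    readr,
    jsonlite,
    ggplot2,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
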