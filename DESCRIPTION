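Package: tricomp
Title: Statistical and Dynamic Models of Triangle Completion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Models of how people locate and reason about the missing corner
    of a fragmented planar triangle. Implements a correlated-random-walk line
    extrapolator, its equivalent worm-like-chain (semi-flexible polymer)
    statistical model with analytic endpoint moments, predictors for
    missing-angle estimates (Gamma moment matching) and for three-way
    categorical judgments about triangle transformations, a straight-line
    noisy-angle null model, scaling-exponent estimation with bootstrap
    confidence intervals, chi-squared goodness of fit and Bayes-factor model
    comparison, and a synthetic behavioral-data generator reproducing the
    structure of five triangle-completion experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
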