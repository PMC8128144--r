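Package: cmaf
Title: Ensemble Prediction of Drug-Disease Associations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts drug-disease associations for drug repositioning by
    completing a sparse binary association matrix with weighted
    K-nearest-known-neighbor profiles, learning linear neighborhood
    similarities by simplex-constrained quadratic programming, running three
    base predictors (label propagation, graph-regularized non-negative matrix
    factorization, and network consistency projection), and fusing their
    scores with a noisy-OR rule. Includes a 10-fold cross-validation and
    de-novo drug hold-out evaluation harness, ranked candidate export, a
    synthetic planted-structure network generator, and a command-line
    interface.
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
    quadprog,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
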