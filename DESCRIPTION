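Package: bdcohort
Title: Detecting Tweets that Report a Child's Birth Defect Outcome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for detecting, among tweets that mention
    birth defects, those in which the user reports their own child's outcome.
    Includes lexicon/regex retrieval with retweet/username/URL post-filters,
    two text-normalization tracks (a stemmed placeholder track for sparse
    feature models and a marker track for sequence models), n-gram,
    word-cluster and length features with min-max scaling and information-gain
    ranking, five data-level class-imbalance strategies built on the
    Levenshtein-ratio similarity, Multinomial Naive Bayes, RBF-kernel SVM and
    LSTM classifiers, a stratified evaluation harness with confusion matrices,
    precision-recall curves and feature ablation, and a seeded generator of
    synthetic labeled tweet corpora for fully offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    Matrix,
    methods,
    purrr,
    rlang,
    stringi,
    stringr,
    tibble,
    tidyr,
    utils,
    stats,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
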