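Package: synergyscreen
Title: Machine-Learning Screening of Synergistic Drug Combinations with
    Median-Effect Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for predicting synergistic small-molecule drug
    combinations from drug-pair similarity and network features. Computes
    sixteen pair features (fingerprint Tanimoto, ADME distance,
    Smith-Waterman target-sequence aggregates, Wang-method GO semantic
    similarity aggregates, enriched-pathway cosine similarity, and
    protein-protein-interaction distance/proximity features), screens them
    by group-difference tests and resampled recursive feature elimination,
    trains an ensemble of classifiers on repeatedly undersampled 1:5
    training sets, ranks candidate pairs by positive votes, and evaluates
    predicted combinations with Chou-Talalay median-effect fits and the
    combination index. Includes a synthetic drug-universe generator with
    planted, recoverable signal for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    class,
    e1071,
    fgsea,
    igraph,
    ranger,
    rpart,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
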