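Package: phigold
Title: Consensus Gold Standards and CRF De-Identification for Clinical Text
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building de-identification gold standards from
    multiple annotators' protected-health-information (PHI) span
    annotations over clinical text, and for training and evaluating a
    linear-chain conditional random field (CRF) de-identifier on them.
    Includes an automatic consensus builder (union, majority vote,
    longest span, label-specificity resolution, singleton inclusion), an
    executable guideline rule engine for manually refined consensus
    sets, pairwise inter-annotator agreement F-scores and agreement
    tables, configurable label-merging schemes, exact (token-level) and
    partial (character-level) match evaluation with
    annotated/retrieved/relevant bookkeeping, a false-positive audit,
    and a seeded synthetic generator of Swedish-flavoured clinical-style
    documents with simulated imperfect annotators, so the whole pipeline
    runs without access to any confidential corpus.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
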