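Package: dnr
Title: Drug Name Recognition with Conjunction Features and Feature Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A feature-engineering pipeline for drug name recognition (DNR) in
    biomedical text. Sentences are labeled over a BILOU tag scheme for four
    entity types (drug, brand, group, no-human) with a linear-chain conditional
    random field. The package implements sixteen singleton feature templates
    (word, part-of-speech, chunk, orthography, dictionary membership, affixes,
    word shapes, word-embedding clusters), two-feature conjunction template
    sets expanded over a five-token context window, per-tag feature selection
    by Chi-square, mutual information and information gain with top-fraction
    retention, entity-level evaluation under strict, exact, type and partial
    matching criteria, plus a seeded synthetic corpus generator so the whole
    pipeline is testable without external corpora or toolkits.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
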