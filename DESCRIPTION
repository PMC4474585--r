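Package: phenoNER
Title: Phenotype Named-Entity Recognition for Clinical and Literature Text
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A toolkit for recognising phenotype concept mentions (causes,
    risk factors, signs and symptoms, and kidney-function-related
    non-traditional risk factors of congestive heart failure) in two styles
    of text: telegraphic discharge summaries and full-sentence literature
    articles. Implements three families of extraction methods behind one
    document model: a token-pattern rule engine, a gazetteer (dictionary)
    tagger with semantic-type filtering, and three BIO sequence labelers
    (a feature-augmented hidden Markov model, a maximum-entropy Markov
    model, and a linear-chain conditional random field) sharing a common
    feature layer with an affix registry harvested from gold annotations.
    Includes exact and relaxed span-matching evaluation, F-score based
    inter-annotator agreement, document-level holdout, k-fold and
    cross-text-type experiment harnesses, standoff and CoNLL-style readers
    and writers, and a seeded synthetic corpus generator so every component
    is testable without access-restricted clinical corpora.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
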