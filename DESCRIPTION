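Package: clinpool
Title: Clinical Concept Extraction with Pooled Annotated Corpora
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how pooling annotated clinical-text corpora
    from institutions with differing annotation guidelines affects machine
    learning concept extraction. Implements an i2b2-style standoff and CoNLL
    corpus model, lexical normalization with exhaustive overlapping
    dictionary lookup, a feature-based linear-chain conditional random field
    tagger for medical-problem phrases, exact- and overlap-span evaluation
    with precision/recall/F1, automated guideline reconciliation (stripping
    leading articles and possessive pronouns), pooled and subset-size
    cross-validation experiment designs with learning curves, and a
    template-based generator of paired synthetic corpora with controllable
    guideline differences.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
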