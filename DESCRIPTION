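Package: chemtagr
Title: Chemical Named Entity Recognition with Conditional Random Fields
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A document-processing pipeline for recognizing chemical and drug
    name mentions in scientific abstracts. Implements chemistry-aware sentence
    splitting and tokenization, a rich token feature set (orthographic,
    morphological, dictionary and local-context conjunction features),
    linear-chain conditional random field models of order 1 and 2 in either
    parsing direction with exact span-level confidence scores, harmonization of
    annotation sets from multiple models, rule-based post-processing
    (parentheses balance filtering, abbreviation resolution, log-odds exclusion
    lists), confidence-ranked mention-level and document-level outputs in
    BioCreative CHEMDNER-style formats, span-matching evaluation under five
    strategies, iterative feature elimination, and a deterministic synthetic
    corpus generator for download-free testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    stringi
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
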