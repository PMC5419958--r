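Package: bitagger
Title: Bidirectional Conditional Random Field Tagger for Gene and Protein
    Mentions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Trainable named-entity recogniser for gene and protein
    mentions in biomedical text.  Implements rich orthographic,
    morphological and affix token features with character N-grams,
    offset conjunctions and a corpus-frequency feature; PCA-based
    selection of sparse indicator features; second-order linear-chain
    conditional random fields trained in both reading directions;
    model combination by union, intersection or margin-infused
    relaxed algorithm (MIRA) weight refinement; and rule-based
    post-processing covering contextual keyword clues, parenthesis
    repair and two-tier abbreviation handling.  Reads and writes
    BioCreative II gene-mention style sentence and annotation files
    and ships a deterministic synthetic corpus generator so the whole
    pipeline is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
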