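Package: dilitext
Title: Hierarchical Classification of Drug-Induced Liver Injury Risk in Drug Labeling Text
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for classifying drug labeling documents by the
    drug-induced liver injury (DILI) risk expressed in their warnings text.
    Implements a two-stage hierarchical pipeline: a liver-context gate
    (string-pattern filter or token-level IOB tagger) followed by a binary
    sentence classifier, with any-positive aggregation to the document
    level and per-sentence provenance. Includes a keyword-dictionary
    baseline, a synthetic labeling-corpus generator with token, sentence
    and document ground truth, class-weight oversampling, occlusion-based
    token attribution, and an evaluation suite (Matthews correlation
    coefficient metrics, repeated stratified cross-validation, permutation
    significance testing).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    Matrix,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
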