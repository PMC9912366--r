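Package: tfmapr
Title: Transcription Factor Network Mapping from Perturbation Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps the direct functional targets of transcription factors (TFs)
    from TF-perturbation gene-expression data. Builds per-edge evidence scores
    (differential expression, LASSO regression, tree-ensemble importance,
    inferred-motif promoter scans), combines them with a gradient-boosted tree
    classifier trained on binary binding labels in generalization, integration
    and cross-trained modes, and evaluates the resulting network maps with
    binding-support, GO-enrichment, GO-directness and protein-interaction
    metrics. Includes a planted-truth synthetic benchmark generator so the
    whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    ranger,
    xgboost,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr
Config/testthat/edition: 3
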