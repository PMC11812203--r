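Package: slcscore
Title: Multi-Omics Confidence Scoring for Solute Carrier Substrate Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts substrates for orphan solute carrier (SLC) transporters
    by integrating expression-metabolite rank correlations from multiple
    cancer cell-line panels, CRISPR gene-dependency contrasts, and
    conversion-step adjacency in the metabolic reaction network into a single
    confidence score benchmarked against permutation nulls. A parallel
    dose-response procedure associates SLC expression with cytotoxic drug
    efficacy from drug-repurposing viability panels. Includes a seeded
    synthetic-panel generator so the whole pipeline runs and is testable
    without access to the original cell-line datasets, plus a subcommand
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    yaml,
    DESeq2
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
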