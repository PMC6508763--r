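Package: boolimpl
Title: Boolean Implication Networks from Gene Expression Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Infers asymmetric and symmetric Boolean implication
    relationships between genes from normalized expression matrices.
    Fits a rising step function to each gene's sorted expression values
    to derive a discretization threshold, calls each value low,
    intermediate or high around that threshold, and classifies ordered
    gene pairs into six implication classes (lolo, lohi, hilo, hihi,
    equivalent, opposite) by testing each quadrant of the joint
    discretized scatter for sparseness. Includes tissue-universe
    evaluation of candidate logical invariants, duplicate-file detection
    by content hashing for meta-analysis quality control, head-to-head
    comparison of two implication networks, and a synthetic-data
    generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    tools,
    utils,
    digest,
    jsonlite,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    openssl
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Network, GeneExpression, Microarray, RNASeq, QualityControl
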