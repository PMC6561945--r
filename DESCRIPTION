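Package: ICRpanel
Title: Immune Panel Profiling with the Immunologic Constant of Rejection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Integrative analysis of targeted immune gene expression panels
    (NanoString nCounter PanCancer Immune Profiling-style) from paired tumor
    biopsies: housekeeping/background/quantile normalization to log2
    expression, single-sample gene set enrichment (ssGSEA) for leukocyte
    signatures, Immunologic Constant of Rejection (ICR) scoring with
    consensus-clustering classification into ICR High/Medium/Low, paired and
    unpaired differential expression with anti-log fold changes and
    Benjamini-Hochberg adjustment, annotation-category enrichment, and
    enrichment-score fold-change summaries. Includes a synthetic paired-design
    data generator with recoverable ground truth so the full pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
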