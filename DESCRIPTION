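Package: rb1x
Title: Integrative Multi-Omics Analysis of RB1 Disruption and Molecular
    Subtypes in Small Cell Carcinoma
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for integrative analysis of tumor-suppressor disruption
    in small cell carcinomas, built around RB1. Implements a seven-rule
    somatic-variant filter cascade for tumor/normal candidate calls
    (including FFPE artifact handling), exon-resolution homozygous
    deletion calling from capture-bin log2 coverage ratios with
    common-CNV reciprocal-overlap filtering, splice-junction abnormality
    classification (exon skipping, gene fusion, novel splice sites,
    3'-terminal expression loss), integration of WES, RNA-seq and IHC
    evidence into per-sample disruption calls, mutational-signature
    extraction by non-negative matrix factorization with an explained
    variance plus reference-cosine rule for choosing the number of
    signatures, consensus-clustering molecular subtyping with Tukey HSD
    signature-gene discovery, and tumor-microenvironment scoring (ssGSEA,
    overall-expression scores, Monte Carlo overlap tests, CD8 immune
    phenotype rules). A synthetic-cohort generator with planted ground
    truth provides every input the pipeline consumes, so the full
    pipeline is testable without access-controlled patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    IRanges,
    S4Vectors,
    limma,
    car
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
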