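Package: scpeqtl
Title: Cell Type-Resolved Pseudobulk eQTL Mapping and Specificity Testing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for cell type-resolved expression quantitative
    trait locus (eQTL) analysis from single-cell RNA-seq data. Implements
    MAD-based cell quality control, per-donor per-cell-type pseudobulk
    aggregation with quantile normalisation and z-transformation, cis-eQTL
    linear-model mapping with a latent expression factor covariate and
    study-wide Benjamini-Hochberg FDR, and a battery of cell type-specificity
    tests: sharing classification with LD linking, conditional independence
    of top eSNPs, SNP-by-cell-type interaction models, eGene expression and
    test-statistic correlations, and permutation rank enrichment. Ships a
    synthetic-data module that simulates LD-structured genotypes and
    negative-binomial single-cell counts with planted genetic effects so
    every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Matrix,
    data.table,
    limma,
    lme4,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
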