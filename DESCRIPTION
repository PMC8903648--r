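Package: phenolink
Title: One-Click Phenotype Association Analysis for Quantitative Omics Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Automated phenotype association analysis for wide-format
    quantitative omics expression matrices (proteins or intact
    glycopeptides) against tagged clinical phenotype tables. Provides
    phenotype profiling and pairwise phenotype correlation,
    preprocessing (log2 transform, median normalization, noise
    filtration, minimum-value imputation) with replicate-based quality
    control, knowledge-database annotation with structured glycoform
    identifier parsing, differential expression with
    Benjamini-Hochberg correction, principal component analysis with a
    variance-ratio-weighted feature contribution score, hierarchical
    feature clustering, per-feature correlation and logistic
    regression with ROC analysis, hypergeometric over-representation
    analysis against GMT gene-set collections, a deterministic
    synthetic-cohort generator, and a one-click pipeline driver that
    emits CSV result tables at every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
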