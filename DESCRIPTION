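Package: tsmr
Title: Two-Sample Mendelian Randomization with Meta-Analysis and Colocalization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for causal inference from GWAS summary
    statistics: instrument selection (p-value thresholding, LD clumping,
    confounder exclusion), exposure-outcome harmonization, five two-sample
    Mendelian randomization estimators (inverse-variance weighted, MR-Egger,
    weighted median, simple and weighted mode) with a full sensitivity battery
    (Cochran's Q, Egger intercept, Steiger directionality, leave-one-out,
    Benjamini-Hochberg FDR), fixed and DerSimonian-Laird random-effects
    meta-analysis of per-study estimates, Bayesian colocalization of two traits
    over a genomic window via Wakefield approximate Bayes factors, and ROC/AUC
    diagnostic evaluation. Includes seed-deterministic simulators for GWAS
    summary statistics, LD-coherent regional associations, and two-group
    expression matrices, so the whole pipeline is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    pROC,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    metafor,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
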