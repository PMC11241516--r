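Package: mirtarnet
Title: Integrated miRNA-Target Network Analysis of Treatment Response
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for the integrated analysis of miRNA and gene expression in
    two-group treatment-response cohorts (responders vs non-responders), as used
    in clear cell renal cell carcinoma patients treated with sunitinib.
    Implements two-group differential expression with fold-change and p-value
    gates, reciprocal-direction integration of differentially expressed miRNAs
    and genes against a table of experimentally validated miRNA-target
    interactions, hypergeometric gene-set over-representation with kappa-score
    grouping of enriched terms, delta-delta-Ct relative quantification of qPCR
    data with replicate-level quality control, logistic biomarker-panel
    combination with midrank ROC/AUC evaluation, Kaplan-Meier/log-rank survival
    comparison with marker dichotomization, and clinical association statistics.
    A seeded synthetic-cohort generator with planted reciprocal miRNA-target
    effects makes every stage testable without access to the original cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    survival,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
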