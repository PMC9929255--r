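Package: macnet
Title: Network-Guided Analysis of Serum-Induced Macrophage Reprogramming
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for detecting circulating-factor-induced
    macrophage reprogramming from bulk transcriptomes and for network-guided
    drug repurposing. Implements per-gene differential expression with
    Benjamini-Hochberg correction, weighted gene co-expression module
    detection with topological overlap and module eigengenes, module-trait
    correlation against clinical outcome variables, mutual-information
    regulatory network inference with bootstrap consensus and data-processing-
    inequality pruning, regulatory-score ranking of candidate driver
    transcription factors, connectivity-map style signature-reversal scoring
    of perturbation profiles, triple feature selection (mRMR, maximal
    information coefficient, differential-expression ranking), stratified
    cross-validated classification, and cross-cohort validation statistics
    (hypergeometric list overlap, single-sample gene-set enrichment). A
    synthetic-cohort generator with planted modules, regulators, trait
    couplings and signature-reversing drugs provides ground truth for
    recovery testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    mixOmics
Config/testthat/edition: 3
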