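Package: netdriver
Title: Hidden Driver Inference from Data-Driven Gene Regulatory Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reverse-engineers context-specific transcription-factor and
    signaling interactomes from expression profiles using mutual information
    with bootstrap consensus and data-processing-inequality pruning, infers
    per-sample driver activity as the signed-MI weighted mean of target
    z-scores, tests differential activity and expression between two phenotype
    groups with moderated-t and Bayesian linear-model statistics, integrates
    evidence across omics modalities by Stouffer's method into a ranked
    per-driver master table, and performs Fisher/GSEA-style functional
    enrichment. Includes a seeded synthetic-data generator that plants hidden
    drivers (shifted activity, unshifted own-gene expression) so the whole
    pipeline can be validated against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
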