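Package: coexmod
Title: Weighted Gene Co-Expression Disease Modules in Whole Blood
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: A tested pipeline for weighted gene co-expression network
    analysis of case/control expression cohorts: probe-level filtering,
    normalization and probe-to-gene collapsing; soft-thresholded adjacency
    and topological overlap; average-linkage module detection; module
    eigengene summarization and covariate-adjusted disease association with
    FDR control; permutation-based module preservation Z statistics between
    cohorts; hypergeometric/Fisher enrichment against marker gene lists,
    brain-expressed gene sets and GWAS SNP windows; and qPCR delta-delta-Ct
    validation arithmetic. Includes a synthetic two-cohort data generator
    with planted module structure, disease and medication effects against
    which every stage of the pipeline can be scored.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    limma,
    stats,
    utils
Suggests:
    jsonlite,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
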