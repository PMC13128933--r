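Package: gxepath
Title: Gene-by-Injury Interaction GWAS, Pathway Enrichment, Network Key
    Drivers, and Pathway Polygenic Risk Scores
Version: 0.1.0
Authors@R:
    person("Workbench", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end toolkit for omnigenic gene-by-environment
    analysis of a continuous phenotype: per-SNP additive and
    SNP-by-injury interaction regression with genomic-control
    diagnostics, linkage-disequilibrium marker dependency filtering,
    distance-based SNP-to-gene mapping, marker-set enrichment analysis
    of full GWAS summary-statistic distributions with a permutation
    null, cell-type gene regulatory network inference from single-cell
    expression via pseudocell aggregation and bootstrapped gradient
    boosting, key-driver detection on network neighborhoods, and
    pathway-based additive/interaction polygenic risk scoring with
    formal model comparison. Includes a synthetic-data generator with
    planted truth for calibration and recovery testing, and a pipeline
    driver with a reproducibility manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    igraph,
    jsonlite,
    Matrix,
    methods,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    GenomicRanges,
    IRanges,
    optparse,
    rtracklayer,
    S4Vectors,
    SummarizedExperiment,
    testthat (>= 3.0.0),
    VariantAnnotation,
    yaml
Config/testthat/edition: 3
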