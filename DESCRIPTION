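Package: cfepiscan
Title: Cell-Free DNA 5mC/5hmC Differential Modification Analysis for
    Case-Control Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Window-based analysis of plasma cell-free DNA methylation (5mC)
    and hydroxymethylation (5hmC) enrichment sequencing in case-control
    designs, built around a schizophrenia-versus-control study layout.
    Provides fragment filtering and length profiling with spike-in capture
    efficiency, a sliding-window count grid with mappability and dark-region
    filters, a covariate-adjusted negative-binomial Wald engine for calling
    differentially (hydroxy)methylated regions, CpG/genic annotation with
    hypergeometric and Fisher gene-set enrichment, GWAS-locus colocalization
    with a randomized-SNP proximity null, brain structural-measure
    association via Spearman screening and sparse canonical correlation
    (penalized matrix decomposition), a cross-validated gradient-boosted
    disease-probability score, and a synthetic-data generator that emulates
    the full data structure so every stage is testable without sequencing
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
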