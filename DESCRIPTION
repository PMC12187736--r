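Package: MethylBurden
Title: Promoter Methylation Burden Scoring and Survival Analysis for
    450K-Style Methylation Arrays
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds gene-level promoter methylation profiles from
    probe-level beta values of Illumina 450K-style arrays, scores each
    sample's repair-gene promoter methylation burden (RPMB, the fraction
    of a designated gene set whose promoters exceed a beta threshold),
    tests the gene set for hypomethylation against resampled
    size-matched null sets and against other named gene sets, and runs
    the downstream clinical statistics: baseline contingency tables with
    chi-square tests, Kaplan-Meier / log-rank survival comparison,
    univariate Cox models and median-split subgroup forest analysis.
    Includes a synthetic cohort generator that emulates the assumed data
    structure (hypomethylated target genes, burden-correlated
    covariates, stratum-specific hazards) so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    survival
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: DNAMethylation, MethylationArray, Survival, Epigenetics,
    GeneSetEnrichment
RoxygenNote: 7.3.3
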