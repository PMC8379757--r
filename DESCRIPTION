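Package: wgbsdmr
Title: Case-Control Germ-Cell Methylome Analysis with Confounder-Aware DMR Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for case-control whole-genome bisulfite
    sequencing (WGBS) analysis of purified germ-cell samples: somatic-DNA purity
    screening via imprinted loci, simplified MethylSeekR-style segmentation of
    methylomes into unmethylated and low-methylated regions, stringent consensus
    differentially-methylated-region (DMR) discovery with two native callers and a
    within-group methylation-range filter against genotype-driven confounders,
    CpG-count- and length-matched Monte Carlo enrichment of DMRs in genomic
    features, DMR-to-gene association, direction-skew binomial statistics, and a
    beta-binomial synthetic cohort generator with planted ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
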