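Package: epiquant
Title: Promoter Bivalency, Factor Co-Occupancy and Differential
    Accessibility on Synthetic Epigenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis of promoter chromatin state in
    embryonic stem cells: the H3K4me3/H3K27me3 promoter ratio statistic
    with knockout-relative ratios and sliding-window correlation to
    expression, multi-factor ChIP-seq peak co-occupancy (Venn fractions
    and seven-way TSS cluster assignment), count-based differential
    accessibility with factor-dependent peak classification, TSS
    meta-profiles with edge-bin background normalization, and a
    fragment-size nucleosome-occupancy summary. Includes a seeded
    synthetic-epigenome generator (genotype-dependent ChIP and ATAC
    fragments, co-binding peak sets, expression counts) with ground-truth
    labels for end-to-end parameter-recovery testing, and a
    configuration-driven pipeline that runs the full analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
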