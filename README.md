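# epiquant

Quantitative downstream analysis of promoter chromatin state in embryonic
stem cells, built around the question: when a chromatin regulator is knocked
out, which gene promoters shift their H3K4me3/H3K27me3 balance and their
accessibility, and are those the lineage (primitive endoderm) genes that
become de-repressed?

The package is for computational biologists who want the analysis stages of
such a study as tested, reusable R components rather than one-off scripts:

* **Promoter bivalency** — for gene *g*, fragment counts for each mark in the
  window `[TSS − 3 kb, TSS + 3 kb)` are CPM-normalized and summarized as the
  pseudo-counted ratio `R_g = (s4 + α) / (s27 + α)` (α = 1 CPM), with
  three-category promoter classification (`K4_only` / `K27_only` /
  `bivalent`), the knockout-relative ratio `R_KO / R_WT`, ranked-gene
  recovery of knockout-responsive promoters, and the sliding-window (width
  100, step 1) Spearman correlation of ratio with expression.
* **Co-occupancy** — two- and three-way Venn overlap of peak sets (≥ 1 bp
  predicate; triple co-binding measured over merged union loci) and the
  seven-way cluster assignment of genes by which of three factors bind
  within ± 4 kb of the TSS.
* **Differential counts** — a documented negative-binomial Wald test with
  median-of-ratios normalization and pooled method-of-moments dispersion,
  Benjamini–Hochberg FDR, the `FDR < 0.05 & |log2FC| > 1` significance rule,
  and factor-dependent vs -independent ATAC peak classification.
* **Signal summaries** — binned coverage, TSS meta-profiles normalized so
  the mean of the first and last five 10-bp bins is 1 (background = 1),
  threshold peak calling, two-of-three replicate reproducibility filtering,
  and a fragment-size nucleosome-occupancy score (sub-nucleosomal < 100 bp
  vs mono-nucleosomal 180–247 bp).
* **Synthetic epigenome** — a seeded generator for the whole input universe
  (gene annotation, genotype-dependent ChIP and ATAC fragments, co-binding
  peak sets, NB expression counts) with ground-truth labels, so every stage
  is validated by parameter recovery.

Objects are Bioconductor-style S4 (`PeakSet`, `FragmentSet`,
`BivalencyTable`, `VennResult`, `SyntheticTruth`, ...) over
`GenomicRanges::GRanges`; files on disk are plain BED / bedGraph / TSV /
JSON.

## Worked example

Two-way peak overlap at published set sizes, then the full pipeline on the
default synthetic epigenome (500 genes, 50 knockout-responsive, 3 replicates
per genotype):

```r
library(epiquant)

fx <- cobindingPairFixture(10642, 11175, 7167, names = c("ADNP", "BRG1"))
intersectPair(fx[[1]], fx[[2]])
#> VennResult (pair)
#>   sizes: ADNP=10642 BRG1=11175
#>   overlaps: ADNP_with_BRG1=7167 BRG1_with_ADNP=7167
#>   percents: ADNP_side=67 BRG1_side=64

report <- runPipeline(list(outDir = "epiquant_out"))
str(report$recovery)
#> List of 5
#>  $ responsiveSensitivity: num 1
#>  $ responsivePrecision  : num 1
#>  $ atacDependentJaccard : num 0.96
#>  $ degTruePositives     : int 48
#>  $ degFalsePositives    : int 1
```

Reading the output: 67% of the 10,642 "ADNP" peaks overlap a "BRG1" peak and
64% of the 11,175 BRG1 peaks overlap an ADNP peak (7,167 one-to-one pairs;
fractions are rounded half-up to whole percents, raw counts retained). In the
pipeline report, ranking genes by knockout-relative promoter ratio and
thresholding at the 90th percentile recovers all 50 truly responsive genes
with no false calls (`sensitivity = precision = 1`); differential ATAC
classification matches the true responsive loci at Jaccard 0.96; and DEG
calling finds 48 of the 50 up-regulated genes with 1 false positive among
450 nulls. The run also writes per-stage TSV/BED/JSON outputs (bivalency
tables, ranked genes, Venn results, cluster assignments, differential
tables, a TSS meta-profile) plus `report.json` and the resolved
`config.json` under `outDir`; identical seed and config reproduce the report
byte-for-byte.

A thin command-line wrapper is included at
`inst/scripts/epiquant-pipeline.R` (`run-all` / `simulate` subcommands).

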