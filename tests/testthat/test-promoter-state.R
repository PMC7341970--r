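mkMark <- function(gr, genotype, mark, chromLen = 1e6) {
  GenomeInfoDb::seqlengths(gr) <-
    setNames(rep(chromLen, length(GenomeInfoDb::seqlevels(gr))),
             GenomeInfoDb::seqlevels(gr))
  FragmentSet(gr, paste0(mark, "_", genotype), genotype,
              paste0("chip:", mark))
}

test_that("promoter signal forms pseudo-counted CPM ratios per gene", {
  genes <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                      tss = c(100000, 300000), strand = "+", length = 1000)
  # equal counts for both marks at g1, K4-only at g2
  k4 <- mkMark(GRanges("chr1", IRanges(c(99000, 99500, 299000, 299500,
                                         300200), width = 300)),
               "control", "H3K4me3")
  k27 <- mkMark(GRanges("chr1", IRanges(c(99000, 99500, 500000, 600000,
                                          700000), width = 300)),
               "control", "H3K27me3")
  tab <- promoterSignal(k4, k27, genes)
  rec <- bivalencyRecords(tab)
  # same library sizes, same window counts at g1 -> ratio exactly 1
  expect_equal(rec$ratio[1], 1)
  expect_equal(rec$log2_ratio[1], 0)
  # zero K27 at g2 -> finite ratio (k4 + alpha)/alpha
  expect_true(is.finite(rec$ratio[2]))
  expect_equal(rec$ratio[2], (cpmNormalize(3, 5) + 1) / 1)
  expect_gt(rec$ratio[2], rec$ratio[1])

  bad <- mkMark(GRanges("chr1", IRanges(1, 300)), "knockout", "H3K27me3")
  expect_error(promoterSignal(k4, bad, genes), "genotype mismatch")
})

test_that("promoter signal equals the hand count->CPM->ratio pipeline", {
  ann <- defaultSim()
  k4 <- defaultChip("H3K4me3", "control")
  k27 <- defaultChip("H3K27me3", "control")
  tab <- promoterSignal(k4, k27, ann$genes)
  rec <- bivalencyRecords(tab)
  win <- tssWindows(ann$genes, 3000)
  i <- c(1L, 57L, 200L, 499L)
  c4 <- vapply(i, function(j) oracleWindowCount(intervals(k4), win[j]), 0L)
  c27 <- vapply(i, function(j) oracleWindowCount(intervals(k27), win[j]), 0L)
  s4 <- c4 * 1e6 / length(intervals(k4))
  s27 <- c27 * 1e6 / length(intervals(k27))
  expect_equal(rec$k4_signal[i], s4)
  expect_equal(rec$ratio[i], (s4 + 1) / (s27 + 1))
})

test_that("ratio is monotone in each mark for fixed pseudo-count", {
  r <- function(k4, k27) (k4 + 1) / (k27 + 1)
  k4s <- seq(0, 100, by = 5)
  expect_true(all(diff(r(k4s, 10)) > 0))
  expect_true(all(diff(r(10, k4s)) < 0))
})

test_that("promoter classification matches truth labels at high accuracy", {
  ann <- defaultSim()
  g <- truthGenes(ann$truth)
  k4 <- defaultChip("H3K4me3", "control")
  k27 <- defaultChip("H3K27me3", "control")
  tab <- promoterSignal(k4, k27, ann$genes)
  thr4 <- backgroundCpmThreshold(k4, ann$genes)
  thr27 <- backgroundCpmThreshold(k27, ann$genes)
  tab <- classifyPromoters(tab, thr4, thr27)
  got <- bivalencyRecords(tab)$class
  want <- c(k4_only = "K4_only", k27_only = "K27_only",
            bivalent = "bivalent", neither = "neither")[g$state]
  expect_gte(mean(got == want), 0.95)

  # rule instances
  t0 <- new("BivalencyTable", genotype = "control", flank = 3000L, alpha = 1,
            records = data.frame(gene_id = c("a", "b", "c", "d"),
                                 k4_signal = c(100, 20, 0, 1),
                                 k27_signal = c(0, 20, 100, 1),
                                 ratio = 1, log2_ratio = 0,
                                 class = NA_character_,
                                 relative_ratio = NA_real_))
  cl <- bivalencyRecords(classifyPromoters(t0, 10, 10))$class
  expect_equal(cl, c("K4_only", "bivalent", "K27_only", "neither"))
})

test_that("relative ratio has identity, inversion and scaling invariances", {
  ann <- defaultSim()
  k4 <- defaultChip("H3K4me3", "control")
  k27 <- defaultChip("H3K27me3", "control")
  tab <- promoterSignal(k4, k27, ann$genes)
  # identity: same table on both sides -> all ones
  id <- bivalencyRecords(relativeRatio(tab, tab))$relative_ratio
  expect_equal(id, rep(1, length(id)))

  k4k <- defaultChip("H3K4me3", "knockout")
  k27k <- defaultChip("H3K27me3", "knockout")
  tabK <- promoterSignal(k4k, k27k, ann$genes)
  ab <- bivalencyRecords(relativeRatio(tabK, tab))$relative_ratio
  ba <- bivalencyRecords(relativeRatio(tab, tabK))$relative_ratio
  expect_equal(ab * ba, rep(1, length(ab)))

  # CPM cancels a global depth factor: ranking unchanged under subsampling
  # is approximate, but an exact invariance holds for the error guards
  mismatch <- promoterSignal(k4, k27, ann$genes[1:100, ])
  expect_error(relativeRatio(tabK, mismatch), "gene-universe")
  wrongAlpha <- promoterSignal(k4, k27, ann$genes, alpha = 2)
  expect_error(relativeRatio(tabK, wrongAlpha), "flank and alpha")
})

test_that("knockout-relative ratios recover the configured K4 fold", {
  ann <- defaultSim()
  cfg <- ann$truth@config
  g <- truthGenes(ann$truth)
  tab <- promoterSignal(defaultChip("H3K4me3", "control"),
                        defaultChip("H3K27me3", "control"), ann$genes)
  tabK <- promoterSignal(defaultChip("H3K4me3", "knockout"),
                         defaultChip("H3K27me3", "knockout"), ann$genes)
  rr <- bivalencyRecords(relativeRatio(tabK, tab))$relative_ratio
  # analytic expectation: background dilution and the knockout library-size
  # shift both attenuate the CPM-based fold below koK4Fold
  genomeLen <- cfg$nChroms * cfg$chromLength
  bg <- cfg$depth * (1 - cfg$chipEnrichmentFraction) / genomeLen *
    (6000 + mean(cfg$chipFragmentSizeRange))
  mu <- cfg$depth * cfg$chipEnrichmentFraction / sum(g$k4_wt)
  extra <- mu * sum(g$k4_ko - g$k4_wt)
  libShift <- (cfg$depth + extra) / cfg$depth
  attenuated <- ((cfg$koK4Fold * mu + bg) / (mu + bg)) / libShift
  expect_lt(abs(median(rr[g$responsive]) - attenuated), 0.3)
  expect_lt(abs(median(rr[!g$responsive]) - 1 / libShift), 0.1)
  expect_gt(median(rr[g$responsive]), 2)

  # ranking: at least 90% of the 50 responsive genes inside the top 75
  ranked <- rankGenesByRatioChange(tabK, tab)
  top75 <- ranked$gene_id[1:75]
  expect_gte(length(intersect(top75, g$gene_id[g$responsive])) / 50, 0.9)

  # 90th-percentile thresholding recovers the responsive set
  thr <- quantile(rr, 0.9)
  pred <- g$gene_id[rr > thr]
  tp <- length(intersect(pred, g$gene_id[g$responsive]))
  expect_gte(tp / sum(g$responsive), 0.9)
  expect_gte(tp / length(pred), 0.8)
})

test_that("ranking is deterministic with gene-id tie-breaks", {
  rec <- data.frame(gene_id = c("g2", "g1", "g3"),
                    k4_signal = 1, k27_signal = 1, ratio = 2, log2_ratio = 1,
                    class = NA_character_, relative_ratio = NA_real_)
  t1 <- new("BivalencyTable", genotype = "knockout", flank = 3000L,
            alpha = 1, records = rec)
  t2 <- new("BivalencyTable", genotype = "control", flank = 3000L,
            alpha = 1, records = rec)
  out <- rankGenesByRatioChange(t1, t2)
  expect_equal(out$gene_id, c("g1", "g2", "g3"))
  expect_equal(out$relative_ratio, rep(1, 3))
})

test_that("sliding-window Spearman handles monotone cases and matches oracle", {
  e <- 1:200
  expect_equal(slidingWindowSpearman(1:200, e)$rho, 1)
  expect_equal(slidingWindowSpearman(200:1, e)$rho, -1)
  expect_error(slidingWindowSpearman(1:50, 1:50, window = 100),
               "smaller window")
  expect_error(slidingWindowSpearman(c(1, NA, 3), c(1, 2, 3), window = 2),
               "finite")

  set.seed(88)
  r <- rlnorm(500); x <- rnorm(500) + 0.5 * log(r)
  got <- slidingWindowSpearman(r, x, window = 100, step = 1)
  expect_equal(got$nWindows, 401L)
  expect_equal(got$rho, oracleSlidingSpearman(r, x, 100L), tolerance = 1e-12)
  # step > 1
  got7 <- slidingWindowSpearman(r, x, window = 100, step = 7)
  expect_equal(got7$rho, oracleSlidingSpearman(r, x, 100L, 7L),
               tolerance = 1e-12)
  # windowing commutes with positive affine transforms of expression
  gotAff <- slidingWindowSpearman(r, 3 * x + 11, window = 100)
  expect_equal(gotAff$rho, got$rho)
})

test_that("bivalency tables round-trip through their TSV format", {
  ann <- defaultSim()
  tab <- promoterSignal(defaultChip("H3K4me3", "control"),
                        defaultChip("H3K27me3", "control"), ann$genes)
  tab <- classifyPromoters(tab, 500, 500)
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeBivalencyTable(tab, tf)
  back <- readBivalencyTable(tf)
  expect_equal(back@genotype, tab@genotype)
  expect_equal(back@flank, tab@flank)
  expect_equal(back@alpha, tab@alpha)
  expect_equal(bivalencyRecords(back)$ratio, bivalencyRecords(tab)$ratio)
  expect_equal(bivalencyRecords(back)$class, bivalencyRecords(tab)$class)
})
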