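mkFrags <- function(gr, chromLen = 1000L) {
  GenomeInfoDb::seqlengths(gr) <-
    setNames(rep(chromLen, length(GenomeInfoDb::seqlevels(gr))),
             GenomeInfoDb::seqlevels(gr))
  FragmentSet(gr, "t", "control", "atac")
}

test_that("coverage binning counts every bin a fragment overlaps", {
  # [0,10) on disk = 1..10 -> only bin 1
  fs <- mkFrags(GRanges("chr1", IRanges(1, 10)))
  tr <- binCoverage(fs, 10)[["chr1"]]
  expect_equal(tr@values[1:3], c(1, 0, 0))

  # [5,15) spans bins 1 and 2
  fs <- mkFrags(GRanges("chr1", IRanges(6, 15)))
  tr <- binCoverage(fs, 10)[["chr1"]]
  expect_equal(tr@values[1:3], c(1, 1, 0))

  # fragment beyond chromosome end is rejected by name
  fs <- FragmentSet(GRanges("chr1", IRanges(995, 1005)), "t", "control",
                    "atac")
  expect_error(binCoverage(fs, 10, chromLengths = c(chr1 = 1000)),
               "beyond the chromosome end")
})

test_that("coverage binning equals the per-fragment loop oracle", {
  set.seed(101)
  n <- 1e4; len <- 5e4; bin <- 25L
  s <- sample.int(len - 600, n, replace = TRUE)
  w <- sample.int(500, n, replace = TRUE)
  fs <- mkFrags(GRanges("chr1", IRanges(s, width = w)), chromLen = len)
  tr <- binCoverage(fs, bin)[["chr1"]]
  expect_equal(tr@values, oracleBinCoverage(s, s + w - 1L, bin,
                                            ceiling(len / bin)))
  # conservation for non-spanning fragments over a tiling partition
  binStart <- seq(1L, len, by = 1000L)
  tiles <- GRanges("chr1", IRanges(binStart, width = 1000L))
  inside <- (s - 1L) %/% 1000L == (s + w - 2L) %/% 1000L
  fsIn <- mkFrags(GRanges("chr1", IRanges(s[inside], width = w[inside])),
                  chromLen = len)
  expect_equal(sum(windowCounts(fsIn, tiles)), sum(inside))
})

test_that("window counting matches a linear-scan oracle on random fixtures", {
  set.seed(77)
  for (i in 1:20) {
    gr <- randomIntervals(200, chromLen = 2e4, maxWidth = 300,
                          chroms = "chr1")
    fs <- FragmentSet(gr, "t", "control", "atac")
    win <- GRanges("chr1", IRanges(sample.int(15000, 1), width = 2000))
    expect_equal(as.integer(windowCounts(fs, win)),
                 oracleWindowCount(gr, win))
  }
})

test_that("CPM and RPKM implement the closed-form normalizations", {
  expect_equal(cpmNormalize(0, 1e6), 0)
  expect_equal(cpmNormalize(5e5, 5e5), 1e6)
  expect_equal(rpkm(0, 1000, 1e6), 0)
  expect_equal(rpkm(1000, 1000, 1e6), 1000)
  set.seed(3)
  cnt <- rpois(50, 200); len <- sample(500:5000, 50); lib <- 2.3e6
  expect_equal(rpkm(cnt, len, lib), cnt * 1e9 / (len * lib))
  expect_equal(cpmNormalize(cnt, lib), cnt * 1e6 / lib)
  expect_error(rpkm(1, 0, 1e6), "geneLength")
  expect_error(cpmNormalize(1, 0), "librarySize")
})

test_that("meta-profile sets uniform background to one and errors sanely", {
  # deterministic uniform tiling: one 10 bp fragment starting at every 10 bp
  s <- seq(1L, 99991L, by = 10L)
  fs <- mkFrags(GRanges("chr1", IRanges(s, width = 10L)), chromLen = 1e5)
  anchors <- GRanges("chr1", IRanges(c(30000L, 50000L, 70000L), width = 1L),
                     strand = c("+", "-", "+"))
  mp <- metaProfile(fs, anchors, flank = 1000L, binSize = 10L)
  expect_equal(mp@values, rep(1, 200), tolerance = 1e-12)
  nb <- length(mp@values)
  expect_equal(mean(c(mp@values[1:5], mp@values[(nb - 4):nb])), 1,
               tolerance = 1e-12)

  expect_error(metaProfile(fs, GRanges(), flank = 1000L), "anchor")
  empty <- mkFrags(GRanges("chr1", IRanges(1, 10)), chromLen = 1e5)
  far <- GRanges("chr1", IRanges(50000L, width = 1L))
  expect_error(metaProfile(empty, far, flank = 1000L), "edge bins")
  expect_error(metaProfile(fs, anchors, flank = 55L), "multiple")
})

test_that("meta-profile orients by strand and concentrates center signal", {
  # mirror-image placements on opposite strands give identical profiles
  fsP <- mkFrags(GRanges("chr1", IRanges(10300, width = 50)), chromLen = 1e5)
  aP <- GRanges("chr1", IRanges(10000, width = 1), strand = "+")
  aM <- GRanges("chr1", IRanges(10000, width = 1), strand = "-")
  # a fragment downstream (+300) of a plus anchor...
  mpP <- metaProfile(fsP, aP, flank = 1000L, normalize = FALSE)
  # ...mirrored around the half-open window (p -> 2c - 1 - p): fragment
  # upstream of a minus anchor
  fsM <- mkFrags(GRanges("chr1", IRanges(9650, width = 50)), chromLen = 1e5)
  mpM <- metaProfile(fsM, aM, flank = 1000L, normalize = FALSE)
  expect_equal(mpP@values, mpM@values)

  # hand-computed 20-fragment fixture: all fragments in the center bin,
  # single 10 bp edge-tiling for the denominator
  ctr <- GRanges("chr1", IRanges(rep(9998, 20), width = 5))
  edge <- GRanges("chr1", IRanges(seq(1L, 99991L, by = 10L), width = 10L))
  fs <- mkFrags(c(ctr, edge), chromLen = 1e5)
  mp <- metaProfile(fs, aP, flank = 500L, binSize = 10L)
  expect_gt(max(mp@values), 10)
  expect_equal(mp@values[1], 1)  # edge bins define the denominator
})

test_that("threshold peak caller finds constructed peaks and is monotone", {
  len <- 1e5L; bin <- 10L
  mk <- function(v, orig = "t") new("CoverageTrack", chrom = "chr1",
                                    binSize = bin, chromLength = len,
                                    values = v, origin = orig)
  base <- rep(5, len / bin)
  expect_length(callPeaksSimple(mk(base), mk(base), 4, 100), 0L)

  # one 500 bp region at 10x background
  v <- base; v[501:550] <- 50
  pk <- callPeaksSimple(mk(v), mk(base), 4, 100)
  expect_length(pk, 1L)
  reg <- GRanges("chr1", IRanges(5001, 5500))
  expect_true(overlapsAny(reg, intervals(pk)))

  # monotone in threshold; lowering minWidth never shrinks the output
  set.seed(12)
  vt <- base + rpois(length(base), 2); vt[201:260] <- 60; vt[801:830] <- 40
  for (th in c(2, 3, 4, 6, 8)) {
    lo <- callPeaksSimple(mk(vt), mk(base), th, 50)
    hi <- callPeaksSimple(mk(vt), mk(base), th + 1, 50)
    expect_true(all(overlapsAny(intervals(hi), intervals(lo))))
    wide <- callPeaksSimple(mk(vt), mk(base), th, 20)
    expect_gte(length(wide), length(lo))
  }
  bad <- new("CoverageTrack", chrom = "chr1", binSize = 20L,
             chromLength = len, values = rep(0, len / 20), origin = "t")
  expect_error(callPeaksSimple(mk(base), bad, 4, 100), "share")
})

test_that("replicate-support filter keeps two-of-three and matches brute force", {
  gr1 <- GRanges("chr1", IRanges(c(100, 5000), width = 200))
  gr2 <- GRanges("chr1", IRanges(150, width = 200))
  gr3 <- GRanges("chr1", IRanges(9000, width = 300))
  reps <- lapply(list(gr1, gr2, gr3), PeakSet)
  out <- reproduciblePeaks(reps, 2L)
  # peak near 100 seen in replicates 1 and 2 -> kept (union coordinates)
  expect_length(out, 1L)
  expect_equal(start(intervals(out)), 100L)
  expect_equal(end(intervals(out)), 349L)
  # peaks only in one replicate -> dropped
  expect_false(any(overlapsAny(GRanges("chr1", IRanges(9000, 9300)),
                               intervals(out))))
  expect_error(reproduciblePeaks(reps, 4L), "exceeds")

  set.seed(55)
  for (i in 1:30) {
    grs <- replicate(3, randomIntervals(40, chromLen = 2e4, maxWidth = 400),
                     simplify = FALSE)
    got <- intervals(reproduciblePeaks(lapply(grs, PeakSet), 2L))
    want <- sort(oracleReproduciblePeaks(grs, 2L))
    expect_equal(as.character(seqnames(got)), as.character(seqnames(want)))
    expect_equal(start(got), start(want))
    expect_equal(end(got), end(want))
  }
})

test_that("nucleosome occupancy respects size bands and flags empty bins", {
  reg <- GRanges("chr1", IRanges(1, 1000))
  sub <- GRanges("chr1", IRanges(seq(10, 400, by = 20), width = 60))
  occ <- nucleosomeOccupancy(FragmentSet(sub, "s", "control", "atac"), reg,
                             binSize = 100)
  covered <- !is.na(occ@occupancy)
  expect_true(all(occ@occupancy[covered] == 0))
  expect_true(any(is.na(occ@occupancy)))  # uncovered bins missing, not 0

  mono <- GRanges("chr1", IRanges(seq(10, 400, by = 20), width = 200))
  occ <- nucleosomeOccupancy(FragmentSet(mono, "s", "control", "atac"), reg,
                             binSize = 100)
  expect_true(all(occ@occupancy[!is.na(occ@occupancy)] == 1))
})

test_that("occupancy peaks co-locate with simulated dyads", {
  ann <- defaultSim()
  truth <- ann$truth
  g <- truthGenes(truth)
  ac <- defaultAtac("control")
  sel <- which(g$state %in% c("k4_only", "bivalent"))[1:25]
  hit <- tot <- 0L
  for (i in sel) {
    reg <- GRanges(g$chrom[i], IRanges(g$tss[i] - 500, g$tss[i] + 499))
    occ <- nucleosomeOccupancy(ac, reg, binSize = 50)
    dyadBins <- (c(-400, -200, 200, 400) + 500) %/% 50 + 1L
    vals <- occ@occupancy[dyadBins]
    hit <- hit + sum(!is.na(vals) & vals > 0.5)
    tot <- tot + length(dyadBins)
    # the nucleosome-depleted region at the TSS stays low
    ndrBins <- (c(-50, 0) + 500) %/% 50 + 1L
    ndrVals <- occ@occupancy[ndrBins]
    expect_true(all(is.na(ndrVals) | ndrVals < 0.5))
  }
  expect_gte(hit / tot, 0.9)
})

test_that("track and profile exports round-trip through text formats", {
  tr <- new("CoverageTrack", chrom = "chr1", binSize = 10L,
            chromLength = 100L, values = c(0, 2, 0, 1, 0, 0, 0, 0, 0, 3),
            origin = "t")
  tf <- withr::local_tempfile(fileext = ".bedGraph")
  writeBedGraph(tr, tf)
  bg <- read.table(tf)
  expect_equal(bg$V2, c(10, 30, 90))
  expect_equal(bg$V4, c(2, 1, 3))

  mp <- new("MetaProfile", flank = 100L, binSize = 10L,
            values = rep(1, 20), nAnchors = 3L, normalized = TRUE)
  tf2 <- withr::local_tempfile(fileext = ".tsv")
  writeMetaProfile(mp, tf2)
  tab <- read.table(tf2, header = TRUE)
  expect_equal(tab$offset[1], -100)
  expect_equal(nrow(tab), 20)
})
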