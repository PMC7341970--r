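# Independent brute-force oracles and small fixture generators.
# Oracles deliberately use naive loops and base arithmetic only, never the
# package's own code paths.

library(GenomicRanges)

randomIntervals <- function(n, chromLen = 1e5, maxWidth = 500,
                            chroms = c("chr1", "chr2")) {
  chr <- sample(chroms, n, replace = TRUE)
  s <- sample.int(chromLen - maxWidth, n, replace = TRUE)
  w <- sample.int(maxWidth, n, replace = TRUE)
  GRanges(chr, IRanges(s, width = w))
}

# number of intervals of A overlapping >= minov bp with >= 1 interval of B
# (all-pairs check; the inner comparison is vectorized over B)
oracleOverlapCount <- function(grA, grB, minov = 1L) {
  ca <- as.character(seqnames(grA)); cb <- as.character(seqnames(grB))
  sa <- start(grA); ea <- end(grA); sb <- start(grB); eb <- end(grB)
  hits <- 0L
  for (i in seq_along(grA)) {
    ov <- pmin(ea[i], eb) - pmax(sa[i], sb) + 1L
    if (any(ca[i] == cb & ov >= minov)) hits <- hits + 1L
  }
  hits
}

# literal Benjamini-Hochberg step-up
oracleBH <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  prev <- 1
  for (k in n:1) {
    val <- min(p[o[k]] * n / k, prev)
    q[o[k]] <- val
    prev <- val
  }
  pmin(q, 1)
}

# Spearman of windowed means, everything by hand (mid-ranks + Pearson formula)
oracleSlidingSpearman <- function(r, e, w, step = 1L) {
  o <- order(e)
  r <- r[o]; e <- e[o]
  n <- length(r)
  starts <- seq(1L, n - w + 1L, by = step)
  wr <- vapply(starts, function(s) sum(r[s:(s + w - 1L)]) / w, 0)
  we <- vapply(starts, function(s) sum(e[s:(s + w - 1L)]) / w, 0)
  midrank <- function(x) {
    colSums(outer(x, x, "<")) + (colSums(outer(x, x, "==")) + 1) / 2
  }
  a <- midrank(wr); b <- midrank(we)
  sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
}

# per-fragment loop coverage: each fragment adds 1 to every bin it overlaps
oracleBinCoverage <- function(starts, ends, binSize, nBins) {
  v <- numeric(nBins)
  for (i in seq_along(starts)) {
    b1 <- (starts[i] - 1L) %/% binSize + 1L
    b2 <- (ends[i] - 1L) %/% binSize + 1L
    for (b in b1:b2) if (b >= 1 && b <= nBins) v[b] <- v[b] + 1
  }
  v
}

# linear scan window count, >= 1 bp overlap
oracleWindowCount <- function(fr, win) {
  fc <- as.character(seqnames(fr)); wc <- as.character(seqnames(win))
  sum(fc == wc & start(fr) <= end(win) & end(fr) >= start(win))
}

# replicate-support filter: merge all intervals (1 bp overlap merges), keep
# merged regions overlapped by peaks from >= minSupport replicates
oracleReproduciblePeaks <- function(grList, minSupport) {
  all <- do.call(c, grList)
  if (!length(all)) return(GRanges())
  df <- data.frame(chr = as.character(seqnames(all)),
                   s = start(all), e = end(all))
  df <- df[order(df$chr, df$s), ]
  merged <- df[1, ]
  if (nrow(df) > 1) for (i in 2:nrow(df)) {
    last <- nrow(merged)
    if (df$chr[i] == merged$chr[last] && df$s[i] <= merged$e[last]) {
      merged$e[last] <- max(merged$e[last], df$e[i])
    } else merged <- rbind(merged, df[i, ])
  }
  keep <- logical(nrow(merged))
  for (m in seq_len(nrow(merged))) {
    sup <- 0L
    for (g in grList) {
      hit <- any(as.character(seqnames(g)) == merged$chr[m] &
                 start(g) <= merged$e[m] & end(g) >= merged$s[m])
      if (hit) sup <- sup + 1L
    }
    keep[m] <- sup >= minSupport
  }
  m <- merged[keep, , drop = FALSE]
  GRanges(m$chr, IRanges(m$s, m$e))
}

# memoized default-configuration simulation shared across test files
.simCache <- new.env(parent = emptyenv())
defaultSim <- function() {
  if (is.null(.simCache$ann)) {
    cfg <- simulationConfig()   # seed 1, 500 genes, 50 responsive
    .simCache$ann <- simulateAnnotation(cfg)
  }
  .simCache$ann
}
defaultChip <- function(mark, genotype, replicate = 1L) {
  key <- paste(mark, genotype, replicate, sep = ".")
  if (is.null(.simCache[[key]]))
    .simCache[[key]] <- simulateChipFragments(defaultSim()$truth, mark,
                                              genotype,
                                              replicate = replicate)
  .simCache[[key]]
}
defaultAtac <- function(genotype, replicate = 1L) {
  key <- paste("atac", genotype, replicate, sep = ".")
  if (is.null(.simCache[[key]]))
    .simCache[[key]] <- simulateAtacFragments(defaultSim()$truth, genotype,
                                              replicate = replicate)
  .simCache[[key]]
}
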