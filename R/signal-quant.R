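#' Bin fragment coverage along chromosomes
#'
#' Each fragment adds 1 to every bin it overlaps (fragment-count convention,
#' not per-bp pileup), so the total added count equals the number of
#' fragment-bin overlaps. Chromosome lengths come from the fragments'
#' `seqlengths` unless supplied.
#'
#' @param frags a [FragmentSet-class].
#' @param binSize bin width in bp (> 0).
#' @param chromLengths optional named vector of chromosome lengths; defaults
#'   to the fragment `seqlengths`.
#' @return named list of [CoverageTrack-class], one per chromosome.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(6, 15),
#'                              seqlengths = c(chr1 = 100))
#' fs <- FragmentSet(gr, "s1", "control", "atac")
#' binCoverage(fs, 10)[["chr1"]]  # bins 1 and 2 each get one count
#' @export
binCoverage <- function(frags, binSize, chromLengths = NULL) {
  stopifnot(is(frags, "FragmentSet"))
  .assertScalarNum(binSize, "binSize")
  binSize <- as.integer(binSize)
  gr <- intervals(frags)
  if (is.null(chromLengths)) {
    chromLengths <- seqlengths(gr)
    if (any(is.na(chromLengths)))
      stop("chromosome lengths unknown; supply 'chromLengths'")
  }
  bad <- which(end(gr) > chromLengths[as.character(seqnames(gr))])
  if (length(bad))
    stop("fragment ", bad[1L], " (", as.character(seqnames(gr))[bad[1L]], ":",
         start(gr)[bad[1L]], "-", end(gr)[bad[1L]],
         ") extends beyond the chromosome end")
  out <- list()
  for (chr in names(chromLengths)) {
    len <- chromLengths[[chr]]
    nb <- ceiling(len / binSize)
    sub <- gr[as.character(seqnames(gr)) == chr]
    vals <- numeric(nb)
    if (length(sub)) {
      # bins spanned by each fragment, via first/last bin index
      b1 <- (start(sub) - 1L) %/% binSize
      b2 <- (end(sub) - 1L) %/% binSize
      idx <- sequence(b2 - b1 + 1L, from = b1 + 1L)
      tab <- tabulate(idx, nbins = nb)
      vals <- as.numeric(tab)
    }
    out[[chr]] <- new("CoverageTrack", chrom = chr, binSize = binSize,
                      chromLength = as.integer(len), values = vals,
                      origin = frags@sampleId)
  }
  out
}

#' Count fragments overlapping windows
#'
#' A fragment counts if it overlaps the window by at least 1 bp; half-open
#' semantics on disk mean an abutting fragment does not count. Strand is
#' ignored.
#'
#' @param frags a [FragmentSet-class].
#' @param windows a `GRanges` of windows.
#' @return integer vector of counts, one per window.
#' @export
windowCounts <- function(frags, windows) {
  stopifnot(is(frags, "FragmentSet"))
  countOverlaps(windows, intervals(frags), ignore.strand = TRUE)
}

#' Counts per million (depth normalization)
#' @param count raw fragment/read count(s).
#' @param librarySize total fragments/reads in the library (> 0).
#' @return `count * 1e6 / librarySize`.
#' @export
cpmNormalize <- function(count, librarySize) {
  .assertScalarNum(librarySize, "librarySize")
  count * 1e6 / librarySize
}

#' Reads per kilobase per million mapped reads
#' @param count raw read count(s).
#' @param geneLength exonic gene length(s) in bp (> 0).
#' @param librarySize total mapped reads (> 0).
#' @return `count * 1e9 / (geneLength * librarySize)`.
#' @export
rpkm <- function(count, geneLength, librarySize) {
  if (any(geneLength <= 0)) stop("geneLength must be > 0")
  .assertScalarNum(librarySize, "librarySize")
  count * 1e9 / (geneLength * librarySize)
}

#' Anchor-centered meta-profile with edge-bin normalization
#'
#' Computes the average fragment count per bin across anchors (TSSs or peak
#' centers), orienting each anchor's profile by its strand (minus-strand
#' profiles are reversed so upstream/downstream are comparable), then divides
#' by the mean of the first five and last five bins so background signal is 1.
#'
#' @param frags a [FragmentSet-class].
#' @param anchors `GRanges` of anchor points (centers are used); strand
#'   orients the profile.
#' @param flank half-width in bp; must be a multiple of `binSize` and at
#'   least `10 * binSize` so the edge bins exist.
#' @param binSize bin width in bp (default 10).
#' @param normalize divide by the edge-bin mean (default `TRUE`).
#' @return a [MetaProfile-class].
#' @export
metaProfile <- function(frags, anchors, flank, binSize = 10L,
                        normalize = TRUE) {
  stopifnot(is(frags, "FragmentSet"))
  if (!length(anchors)) stop("at least one anchor is required")
  .assertScalarNum(flank, "flank")
  binSize <- as.integer(binSize)
  if (flank %% binSize != 0) stop("flank must be a multiple of binSize")
  if (flank < 10L * binSize) stop("flank must be >= 10 * binSize")
  nBins <- as.integer(2L * flank %/% binSize)
  centers <- (start(anchors) + end(anchors)) %/% 2L
  nA <- length(anchors)
  binStart <- rep(centers - flank, each = nBins) +
    rep((seq_len(nBins) - 1L) * binSize, times = nA)
  binsGR <- GRanges(rep(as.character(seqnames(anchors)), each = nBins),
                    IRanges(binStart, width = binSize))
  cnt <- countOverlaps(binsGR, intervals(frags), ignore.strand = TRUE)
  m <- matrix(cnt, nrow = nA, ncol = nBins, byrow = TRUE)
  minus <- as.character(strand(anchors)) == "-"
  if (any(minus)) m[minus, ] <- m[minus, nBins:1, drop = FALSE]
  avg <- colMeans(m)
  normalized <- FALSE
  if (normalize) {
    edge <- mean(c(avg[1:5], avg[(nBins - 4L):nBins]))
    if (edge == 0)
      stop("normalization error: zero signal in the edge bins")
    avg <- avg / edge
    normalized <- TRUE
  }
  new("MetaProfile", flank = as.integer(flank), binSize = binSize,
      values = avg, nAnchors = nA, normalized = normalized)
}

#' Threshold-based peak calling on binned coverage (plumbing)
#'
#' A deliberately simple caller for synthetic data: after scaling the control
#' track to the treatment library size, maximal runs of bins whose
#' pseudo-counted fold ratio `(t + 1) / (c + 1)` reaches `foldThreshold` are
#' reported, merged across gaps of at most one bin, and filtered to a minimum
#' width. This is not a model-based caller (no local background model).
#'
#' @param treatment,control [CoverageTrack-class] objects sharing chromosome
#'   and bin size.
#' @param foldThreshold minimum treatment/control fold ratio.
#' @param minWidth minimum peak width in bp.
#' @param name label for the resulting [PeakSet-class].
#' @return a [PeakSet-class] (possibly empty).
#' @export
callPeaksSimple <- function(treatment, control, foldThreshold, minWidth,
                            name = "peaks") {
  stopifnot(is(treatment, "CoverageTrack"), is(control, "CoverageTrack"))
  if (treatment@binSize != control@binSize ||
      treatment@chrom != control@chrom ||
      length(treatment@values) != length(control@values))
    stop("treatment and control tracks must share chromosome and bins")
  libT <- sum(treatment@values)
  libC <- sum(control@values)
  scale <- if (libC > 0) libT / libC else 1
  ratio <- (treatment@values + 1) / (control@values * scale + 1)
  keep <- ratio >= foldThreshold
  if (!any(keep)) return(PeakSet(GRanges(), name = name))
  r <- rle(keep)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  # merge runs separated by gaps of <= 1 bin
  merged <- runs[1, , drop = FALSE]
  if (nrow(runs) > 1) {
    for (i in 2:nrow(runs)) {
      if (runs$start[i] - merged$end[nrow(merged)] <= 2L)
        merged$end[nrow(merged)] <- runs$end[i]
      else merged <- rbind(merged, runs[i, ])
    }
  }
  bs <- treatment@binSize
  gs <- (merged$start - 1L) * bs + 1L
  ge <- pmin(merged$end * bs, treatment@chromLength)
  keepW <- (ge - gs + 1L) >= minWidth
  gr <- GRanges(treatment@chrom, IRanges(gs[keepW], ge[keepW]))
  PeakSet(gr, name = name)
}

#' Replicate-reproducible peaks
#'
#' Merges all replicate peaks (1 bp overlap merges) and keeps each merged
#' interval when peaks from at least `minSupport` replicates overlap it; the
#' retained coordinates are the union of the supporting peaks. This realizes
#' the "detected in at least two out of three replicates" filter.
#'
#' @param replicateSets list of [PeakSet-class], one per replicate.
#' @param minSupport minimum number of supporting replicates (default 2).
#' @param name label for the output set.
#' @return a [PeakSet-class] of merged, supported intervals.
#' @export
reproduciblePeaks <- function(replicateSets, minSupport = 2L, name = "consensus") {
  if (minSupport > length(replicateSets))
    stop("minSupport (", minSupport, ") exceeds the number of replicates (",
         length(replicateSets), ")")
  grl <- lapply(replicateSets, intervals)
  all <- do.call(c, lapply(grl, granges))
  if (!length(all)) return(PeakSet(GRanges(), name = name))
  merged <- reduce(all, ignore.strand = TRUE, min.gapwidth = 0L)
  support <- Reduce(`+`, lapply(grl, function(g)
    as.integer(overlapsAny(merged, g, ignore.strand = TRUE))))
  PeakSet(merged[support >= minSupport], name = name)
}

#' Fragment-size nucleosome occupancy over a region
#'
#' A documented simplification of signal-decomposition nucleosome callers:
#' per bin, occupancy is the number of mono-nucleosome-sized fragments over
#' the number of band-assignable fragments (mono + sub-nucleosomal), with
#' each fragment assigned to the bin containing its midpoint. Bins with no
#' band-assignable fragments are `NA` (missing), never 0. Fragments outside
#' both bands are ignored.
#'
#' @param atac a [FragmentSet-class] of ATAC fragments.
#' @param region a length-1 `GRanges` region.
#' @param binSize bin width in bp.
#' @param bands list with `sub` and `mono` size intervals in bp (closed);
#'   defaults to the conventional `< 100` and `180-247` bands.
#' @return a [NucleosomeProfile-class].
#' @export
nucleosomeOccupancy <- function(atac, region, binSize = 50L,
                                bands = list(sub = c(1L, 99L),
                                             mono = c(180L, 247L))) {
  stopifnot(is(atac, "FragmentSet"), length(region) == 1L)
  binSize <- as.integer(binSize)
  gr <- intervals(atac)
  gr <- gr[as.character(seqnames(gr)) == as.character(seqnames(region))]
  mid <- (start(gr) + end(gr)) %/% 2L
  inReg <- mid >= start(region) & mid <= end(region)
  gr <- gr[inReg]; mid <- mid[inReg]
  sz <- width(gr)
  isSub <- sz >= bands$sub[1] & sz <= bands$sub[2]
  isMono <- sz >= bands$mono[1] & sz <= bands$mono[2]
  nBins <- ceiling(width(region) / binSize)
  binIdx <- (mid - start(region)) %/% binSize + 1L
  nS <- tabulate(binIdx[isSub], nbins = nBins)
  nM <- tabulate(binIdx[isMono], nbins = nBins)
  tot <- nS + nM
  occ <- ifelse(tot == 0, NA_real_, nM / tot)
  new("NucleosomeProfile", region = granges(region), binSize = binSize,
      occupancy = occ, bands = bands)
}

#' Export a CoverageTrack as bedGraph
#' @param track a [CoverageTrack-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeBedGraph <- function(track, path) {
  stopifnot(is(track, "CoverageTrack"))
  n <- length(track@values)
  s <- (seq_len(n) - 1L) * track@binSize
  e <- pmin(s + track@binSize, track@chromLength)
  keep <- track@values != 0
  utils::write.table(
    data.frame(track@chrom, s[keep], e[keep], track@values[keep]),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Export a MetaProfile as TSV (bin offset from anchor, value)
#' @param profile a [MetaProfile-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeMetaProfile <- function(profile, path) {
  stopifnot(is(profile, "MetaProfile"))
  n <- length(profile@values)
  offset <- -profile@flank + (seq_len(n) - 1L) * profile@binSize
  utils::write.table(data.frame(offset = offset, value = profile@values),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
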