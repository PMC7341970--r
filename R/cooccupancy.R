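#' Pairwise peak-set overlap (two-way Venn)
#'
#' A peak of A overlaps if it shares at least `minOverlap` bp (default 1)
#' with at least one peak of B, and symmetrically. Per-side counts can differ
#' when overlaps are not one-to-one; both are reported, with per-side
#' fractions and their whole-percent (half-up) rounding for report parity
#' with printed statements.
#'
#' @param A,B [PeakSet-class] objects.
#' @param minOverlap minimum overlap in bp for the predicate (default 1).
#' @return a [VennResult-class] of kind `"pair"`.
#' @examples
#' fx <- cobindingPairFixture(10642, 11175, 7167)
#' vennPercents(intersectPair(fx[[1]], fx[[2]]))  # 67 and 64
#' @export
intersectPair <- function(A, B, minOverlap = 1L) {
  stopifnot(is(A, "PeakSet"), is(B, "PeakSet"))
  ga <- intervals(A); gb <- intervals(B)
  aHit <- sum(countOverlaps(ga, gb, minoverlap = minOverlap,
                            ignore.strand = TRUE) > 0)
  bHit <- sum(countOverlaps(gb, ga, minoverlap = minOverlap,
                            ignore.strand = TRUE) > 0)
  nA <- length(ga); nB <- length(gb)
  if (nA == 0L || nB == 0L)
    warning("empty peak set in overlap comparison; fractions reported as 0")
  fr <- c(A_in_B = if (nA) aHit / nA else 0,
          B_in_A = if (nB) bHit / nB else 0)
  names(fr) <- paste(c(A@name, B@name), "side", sep = "_")
  sizes <- c(nA, nB); names(sizes) <- c(A@name, B@name)
  cnts <- c(as.integer(aHit), as.integer(bHit))
  names(cnts) <- paste(c(A@name, B@name), "with",
                       c(B@name, A@name), sep = "_")
  new("VennResult", kind = "pair", setSizes = sizes, overlapCounts = cnts,
      unionSize = NA_integer_, fractions = fr,
      percents = .halfUpPercent(fr))
}

#' Three-way peak-set overlap via merged union loci
#'
#' All intervals from the three sets are merged (1 bp overlap merges); each
#' merged locus is labelled by which source sets contribute a peak to it. The
#' co-bound fraction is the number of loci labelled by all three over the
#' merged-union locus count.
#'
#' @param A,B,C [PeakSet-class] objects.
#' @return a [VennResult-class] of kind `"triple"` with per-combination locus
#'   counts.
#' @export
intersectTriple <- function(A, B, C) {
  stopifnot(is(A, "PeakSet"), is(B, "PeakSet"), is(C, "PeakSet"))
  grl <- list(intervals(A), intervals(B), intervals(C))
  merged <- reduce(do.call(c, lapply(grl, granges)), ignore.strand = TRUE,
                   min.gapwidth = 0L)
  hit <- vapply(grl, function(g) overlapsAny(merged, g, ignore.strand = TRUE),
                logical(length(merged)))
  if (is.null(dim(hit))) hit <- matrix(hit, ncol = 3L)
  key <- hit[, 1] * 4L + hit[, 2] * 2L + hit[, 3]
  combos <- c("A", "B", "C", "AB", "AC", "BC", "ABC")
  keys <-  c(4L,  2L,  1L,  6L,   5L,   3L,   7L)
  cnts <- vapply(keys, function(k) sum(key == k), integer(1))
  names(cnts) <- combos
  nU <- length(merged)
  frac <- c(cobound = if (nU) cnts[["ABC"]] / nU else 0)
  sizes <- vapply(grl, length, integer(1))
  names(sizes) <- c(A@name, B@name, C@name)
  new("VennResult", kind = "triple", setSizes = sizes,
      overlapCounts = cnts, unionSize = as.integer(nU),
      fractions = frac, percents = .halfUpPercent(frac))
}

#' Assign genes to seven factor-combination TSS clusters
#'
#' For each gene, membership in each factor is whether any of that factor's
#' peaks overlaps the symmetric `tss +/- flank` window (default 4 kb). The
#' membership triple maps to cluster labels: A = factor1 only, B = factor2
#' only, C = factor3 only, D = 1+2, E = 1+3, F = 2+3, G = all three; genes
#' bound by none get `none`. The labels partition the gene universe.
#'
#' @param genes gene annotation `data.frame`.
#' @param peaksA,peaksB,peaksC [PeakSet-class] for the three factors.
#' @param flank window half-width in bp (default 4000).
#' @return `data.frame` (`gene_id`, `cluster`) with a `flank` attribute.
#' @export
assignTssClusters <- function(genes, peaksA, peaksB, peaksC, flank = 4000L) {
  .assertScalarNum(flank, "flank")
  win <- tssWindows(genes, flank)
  mA <- overlapsAny(win, intervals(peaksA), ignore.strand = TRUE)
  mB <- overlapsAny(win, intervals(peaksB), ignore.strand = TRUE)
  mC <- overlapsAny(win, intervals(peaksC), ignore.strand = TRUE)
  key <- paste0(as.integer(mA), as.integer(mB), as.integer(mC))
  map <- c("100" = "A", "010" = "B", "001" = "C", "110" = "D",
           "101" = "E", "011" = "F", "111" = "G", "000" = "none")
  out <- data.frame(gene_id = genes$gene_id,
                    cluster = factor(unname(map[key]),
                                     levels = c(LETTERS[1:7], "none")),
                    stringsAsFactors = FALSE)
  attr(out, "flank") <- as.integer(flank)
  out
}

#' Overlap of factor-dependent accessibility peak sets
#'
#' Identical semantics to [intersectPair()], provided as a named stage so
#' pipeline reports label the comparison of knockout-dependent ATAC
#' hypersensitive peaks between factors. An empty input yields zero fractions
#' with a warning rather than an error.
#'
#' @param depA,depB [PeakSet-class] of factor-dependent accessibility peaks
#'   (outputs of [classifyDependentPeaks()]).
#' @param minOverlap minimum overlap in bp.
#' @return a [VennResult-class].
#' @export
dependentPeakOverlap <- function(depA, depB, minOverlap = 1L) {
  intersectPair(depA, depB, minOverlap = minOverlap)
}

#' Export a VennResult as JSON
#' @param x a [VennResult-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeVennResult <- function(x, path) {
  stopifnot(is(x, "VennResult"))
  jsonlite::write_json(list(kind = x@kind, setSizes = as.list(x@setSizes),
                            overlapCounts = as.list(x@overlapCounts),
                            unionSize = x@unionSize,
                            fractions = as.list(x@fractions),
                            percents = as.list(x@percents)),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
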