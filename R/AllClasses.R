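#' @import methods
#' @importFrom GenomicRanges GRanges GRangesList seqnames start end width strand
#'   findOverlaps countOverlaps reduce granges mcols mcols<-
#' @importFrom IRanges IRanges overlapsAny
#' @importFrom S4Vectors queryHits subjectHits DataFrame
#' @importFrom GenomeInfoDb seqlengths seqlengths<- seqlevels
NULL

setClassUnion("characterOrNULL", c("character", "NULL"))

#' PeakSet: a named collection of genomic peaks
#'
#' A sorted set of strand-aware genomic intervals labelled with the factor or
#' condition they were called for, optionally tagged with a replicate id.
#' Intervals are held as a [GenomicRanges::GRanges] (1-based, closed); on-disk
#' BED files use the usual 0-based half-open convention and are converted by
#' [readBed()]/[writeBed()].
#'
#' @slot name factor/condition label (length-1 character).
#' @slot replicateId replicate label, `NA_character_` when not applicable.
#' @slot ranges `GRanges` of peak intervals, sorted by (chrom, start).
#'
#' @seealso [PeakSet()], [readBed()], [intersectPair()]
#' @export
setClass("PeakSet",
  slots = c(name = "character", replicateId = "character", ranges = "GRanges"))

setValidity("PeakSet", function(object) {
  msg <- character()
  if (length(object@name) != 1L) msg <- c(msg, "'name' must be length 1")
  if (length(object@replicateId) != 1L)
    msg <- c(msg, "'replicateId' must be length 1")
  r <- object@ranges
  if (length(r)) {
    if (any(width(r) < 1L)) msg <- c(msg, "all intervals must have width >= 1")
    o <- order(as.character(seqnames(r)), start(r))
    if (!identical(o, seq_along(r)))
      msg <- c(msg, "intervals must be sorted by (chrom, start)")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a PeakSet
#'
#' @param ranges a `GRanges` of peak intervals (sorted internally).
#' @param name factor/condition label.
#' @param replicateId optional replicate label.
#' @return A [PeakSet-class] object.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(150, 101), width = 50))
#' PeakSet(gr, name = "factorA")
#' @export
PeakSet <- function(ranges, name = "peaks", replicateId = NA_character_) {
  o <- order(as.character(seqnames(ranges)), start(ranges))
  new("PeakSet", name = as.character(name),
      replicateId = as.character(replicateId), ranges = ranges[o])
}

#' FragmentSet: sequenced fragments for one sample
#'
#' Fragment intervals from one ChIP or ATAC library; fragment size is the
#' interval width. Genotype and assay labels come from closed vocabularies so
#' downstream stages can refuse mismatched comparisons.
#'
#' @slot sampleId sample label.
#' @slot genotype `"control"` or `"knockout"`.
#' @slot assay `"atac"` or `"chip:<mark-or-factor>"`.
#' @slot ranges `GRanges` of fragment intervals.
#' @seealso [FragmentSet()], [fragmentSizes()], [binCoverage()]
#' @export
setClass("FragmentSet",
  slots = c(sampleId = "character", genotype = "character",
            assay = "character", ranges = "GRanges"))

setValidity("FragmentSet", function(object) {
  msg <- character()
  if (!object@genotype %in% c("control", "knockout"))
    msg <- c(msg, "genotype must be 'control' or 'knockout'")
  if (!grepl("^(atac|chip:.+)$", object@assay))
    msg <- c(msg, "assay must be 'atac' or 'chip:<label>'")
  if (length(object@ranges) && any(width(object@ranges) < 1L))
    msg <- c(msg, "all fragment sizes must be > 0")
  if (length(msg)) msg else TRUE
})

#' Construct a FragmentSet
#' @param ranges `GRanges` of fragments.
#' @param sampleId sample label.
#' @param genotype `"control"` or `"knockout"`.
#' @param assay `"atac"` or `"chip:<mark>"`.
#' @return A [FragmentSet-class] object.
#' @export
FragmentSet <- function(ranges, sampleId, genotype, assay) {
  new("FragmentSet", sampleId = as.character(sampleId),
      genotype = as.character(genotype), assay = as.character(assay),
      ranges = ranges)
}

#' CoverageTrack: binned fragment counts along one chromosome
#'
#' @slot chrom chromosome name.
#' @slot binSize bin width in bp.
#' @slot chromLength chromosome length in bp.
#' @slot values per-bin fragment counts (or normalized signal); length
#'   `ceiling(chromLength / binSize)`.
#' @slot origin sample id the track was computed from.
#' @seealso [binCoverage()], [callPeaksSimple()], [writeBedGraph()]
#' @export
setClass("CoverageTrack",
  slots = c(chrom = "character", binSize = "integer",
            chromLength = "integer", values = "numeric", origin = "character"))

setValidity("CoverageTrack", function(object) {
  msg <- character()
  if (object@binSize < 1L) msg <- c(msg, "binSize must be >= 1")
  if (any(object@values < 0)) msg <- c(msg, "values must be >= 0")
  if (length(object@values) != ceiling(object@chromLength / object@binSize))
    msg <- c(msg, "length(values) must equal ceiling(chromLength/binSize)")
  if (length(msg)) msg else TRUE
})

#' MetaProfile: anchor-averaged binned signal
#'
#' Average fragment count per bin across a set of anchors (TSSs or peak
#' centers), oriented by anchor strand. When normalized, the signal is divided
#' by the mean of the first five and last five bins so that background is 1.
#'
#' @slot flank half-width of the profiled window in bp.
#' @slot binSize bin width in bp.
#' @slot values averaged (optionally normalized) signal per bin; length
#'   `2 * flank / binSize`.
#' @slot nAnchors number of anchors averaged over.
#' @slot normalized whether edge-bin normalization was applied.
#' @seealso [metaProfile()]
#' @export
setClass("MetaProfile",
  slots = c(flank = "integer", binSize = "integer", values = "numeric",
            nAnchors = "integer", normalized = "logical"))

setValidity("MetaProfile", function(object) {
  msg <- character()
  if (length(object@values) != 2L * object@flank %/% object@binSize)
    msg <- c(msg, "length(values) must equal 2*flank/binSize")
  if (object@nAnchors < 1L) msg <- c(msg, "nAnchors must be >= 1")
  if (length(msg)) msg else TRUE
})

#' NucleosomeProfile: fragment-size nucleosome occupancy over a region
#'
#' Per-bin occupancy score: the fraction of band-assignable fragments (by
#' midpoint) that are mono-nucleosome sized. Bins with no band-assignable
#' fragments are `NA` (missing), never 0.
#'
#' @slot region the profiled `GRanges` region (length 1).
#' @slot binSize bin width in bp.
#' @slot occupancy per-bin score in `[0, 1]` or `NA`.
#' @slot bands list with `sub` and `mono` fragment-size bands (bp).
#' @seealso [nucleosomeOccupancy()]
#' @export
setClass("NucleosomeProfile",
  slots = c(region = "GRanges", binSize = "integer", occupancy = "numeric",
            bands = "list"))

setValidity("NucleosomeProfile", function(object) {
  v <- object@occupancy
  if (any(v < 0 | v > 1, na.rm = TRUE)) "occupancy must lie in [0,1]" else TRUE
})

#' BivalencyTable: per-gene promoter H3K4me3/H3K27me3 state
#'
#' One row per gene with depth-normalized window signal for each mark, the
#' pseudo-counted K4/K27 ratio, its log2, the promoter class, and (when two
#' genotypes have been compared) the knockout-relative ratio. The flank and
#' pseudo-count used are recorded on the object and in every exported table.
#'
#' @slot genotype genotype the table was computed for.
#' @slot flank promoter window half-width in bp (default 3000).
#' @slot alpha pseudo-count added to both CPM signals.
#' @slot records `data.frame` with columns `gene_id`, `k4_signal`,
#'   `k27_signal`, `ratio`, `log2_ratio`, `class`, `relative_ratio`.
#' @seealso [promoterSignal()], [relativeRatio()], [classifyPromoters()]
#' @export
setClass("BivalencyTable",
  slots = c(genotype = "character", flank = "integer", alpha = "numeric",
            records = "data.frame"))

setValidity("BivalencyTable", function(object) {
  msg <- character()
  req <- c("gene_id", "k4_signal", "k27_signal", "ratio", "log2_ratio",
           "class", "relative_ratio")
  if (!all(req %in% names(object@records)))
    msg <- c(msg, paste("records must have columns:", paste(req, collapse = ", ")))
  else {
    if (anyDuplicated(object@records$gene_id))
      msg <- c(msg, "one record per gene required")
    if (any(object@records$ratio <= 0, na.rm = TRUE))
      msg <- c(msg, "ratio must be > 0")
  }
  if (length(msg)) msg else TRUE
})

#' VennResult: multi-set peak overlap summary
#'
#' @slot kind `"pair"` or `"triple"`.
#' @slot setSizes named peak-set sizes.
#' @slot overlapCounts named overlap counts. For a pair: `A_with_B` (A-side
#'   peaks with at least one B partner) and `B_with_A`. For a triple: merged
#'   union loci covered by each source combination, including `ABC`.
#' @slot unionSize number of merged union loci (`NA` for pairs).
#' @slot fractions raw per-side (or co-bound) overlap fractions in `[0, 1]`.
#' @slot percents the same fractions rounded half-up to whole percent, for
#'   report parity with printed "67%"-style statements.
#' @seealso [intersectPair()], [intersectTriple()], [dependentPeakOverlap()]
#' @export
setClass("VennResult",
  slots = c(kind = "character", setSizes = "integer",
            overlapCounts = "integer", unionSize = "integer",
            fractions = "numeric", percents = "numeric"))

setValidity("VennResult", function(object) {
  msg <- character()
  if (any(object@fractions < 0 | object@fractions > 1, na.rm = TRUE))
    msg <- c(msg, "fractions must lie in [0,1]")
  if (length(msg)) msg else TRUE
})

#' SyntheticTruth: ground-truth labels for a simulated epigenome
#'
#' @slot genes per-gene `data.frame`: annotation columns (`gene_id`, `chrom`,
#'   `tss`, `strand`, `length`), promoter `state`, `responsive` flag, realized
#'   per-genotype window intensities (`k4_wt`, `k27_wt`, `k4_ko`, `k27_ko`,
#'   `atac_wt`, `atac_ko`), and the factor-membership triple
#'   (`factorA`/`factorB`/`factorC` logicals).
#' @slot factorPeaks `GRangesList` of true binding windows per factor.
#' @slot dyads `GRanges` of true nucleosome dyad positions (width 1).
#' @slot enhancers `GRanges` of enhancer intervals with `gene_id` and `state`
#'   (`poised`/`active`) metadata.
#' @slot config the [simulationConfig()] the truth was generated from.
#' @seealso [simulateAnnotation()], [emitTruePeaks()]
#' @export
setClass("SyntheticTruth",
  slots = c(genes = "data.frame", factorPeaks = "GRangesList",
            dyads = "GRanges", enhancers = "GRanges", config = "list"))

setValidity("SyntheticTruth", function(object) {
  g <- object@genes
  msg <- character()
  if (any(g$responsive & g$state != "bivalent"))
    msg <- c(msg, "every responsive gene must be bivalent")
  if (length(msg)) msg else TRUE
})

## ---- accessors ----

#' @describeIn PeakSet-class number of peaks.
#' @param x,object a `PeakSet`.
#' @export
setMethod("length", "PeakSet", function(x) length(x@ranges))

#' Peak intervals of a PeakSet
#' @param x a `PeakSet` or `FragmentSet`.
#' @return `GRanges` of intervals.
#' @export
setGeneric("intervals", function(x) standardGeneric("intervals"))

#' @rdname intervals
#' @export
setMethod("intervals", "PeakSet", function(x) x@ranges)

#' @rdname intervals
#' @export
setMethod("intervals", "FragmentSet", function(x) x@ranges)

#' Fragment sizes (bp) of a FragmentSet
#' @param x a [FragmentSet-class].
#' @return integer vector of sizes (`end - start` in half-open terms).
#' @export
fragmentSizes <- function(x) {
  stopifnot(is(x, "FragmentSet"))
  width(x@ranges)
}

#' Genotype label of a FragmentSet or BivalencyTable
#' @param x object with a genotype slot.
#' @return character genotype label.
#' @export
genotypeOf <- function(x) x@genotype

#' Per-gene records of a BivalencyTable
#' @param x a [BivalencyTable-class].
#' @return `data.frame` of per-gene records.
#' @export
bivalencyRecords <- function(x) {
  stopifnot(is(x, "BivalencyTable"))
  x@records
}

#' Ground-truth gene table of a SyntheticTruth
#' @param x a [SyntheticTruth-class].
#' @return `data.frame` with per-gene labels.
#' @export
truthGenes <- function(x) {
  stopifnot(is(x, "SyntheticTruth"))
  x@genes
}

#' Overlap percentages of a VennResult
#' @param x a [VennResult-class].
#' @return named numeric vector of whole-percent overlap fractions.
#' @export
vennPercents <- function(x) {
  stopifnot(is(x, "VennResult"))
  x@percents
}

## ---- show methods ----

setMethod("show", "PeakSet", function(object) {
  cat(sprintf("PeakSet '%s'%s: %d peaks on %d chromosome(s)\n",
              object@name,
              if (is.na(object@replicateId)) ""
              else paste0(" [rep ", object@replicateId, "]"),
              length(object@ranges),
              length(unique(as.character(seqnames(object@ranges))))))
})

setMethod("show", "FragmentSet", function(object) {
  cat(sprintf("FragmentSet '%s' (%s, %s): %d fragments, median size %d bp\n",
              object@sampleId, object@genotype, object@assay,
              length(object@ranges),
              if (length(object@ranges))
                as.integer(stats::median(width(object@ranges))) else 0L))
})

setMethod("show", "CoverageTrack", function(object) {
  cat(sprintf("CoverageTrack %s: %d bins of %d bp (origin %s)\n",
              object@chrom, length(object@values), object@binSize,
              object@origin))
})

setMethod("show", "MetaProfile", function(object) {
  cat(sprintf("MetaProfile: +/-%d bp, %d bins of %d bp, %d anchors%s\n",
              object@flank, length(object@values), object@binSize,
              object@nAnchors,
              if (object@normalized) " (edge-normalized)" else ""))
})

setMethod("show", "BivalencyTable", function(object) {
  cls <- table(factor(object@records$class,
                      levels = c("K4_only", "K27_only", "bivalent", "neither")))
  cat(sprintf(
    "BivalencyTable (%s): %d genes, flank %d bp, alpha %g\n  classes: %s\n",
    object@genotype, nrow(object@records), object@flank, object@alpha,
    paste(names(cls), as.integer(cls), sep = "=", collapse = " ")))
})

setMethod("show", "VennResult", function(object) {
  cat(sprintf("VennResult (%s)\n  sizes: %s\n  overlaps: %s\n  percents: %s\n",
              object@kind,
              paste(names(object@setSizes), object@setSizes, sep = "=",
                    collapse = " "),
              paste(names(object@overlapCounts), object@overlapCounts,
                    sep = "=", collapse = " "),
              paste(names(object@percents), object@percents, sep = "=",
                    collapse = " ")))
})

setMethod("show", "SyntheticTruth", function(object) {
  st <- table(object@genes$state)
  cat(sprintf(
    "SyntheticTruth: %d genes (%s), %d responsive, %d dyads, %d enhancers\n",
    nrow(object@genes),
    paste(names(st), as.integer(st), sep = "=", collapse = " "),
    sum(object@genes$responsive), length(object@dyads),
    length(object@enhancers)))
})
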