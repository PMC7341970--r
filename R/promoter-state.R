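#' Promoter H3K4me3/H3K27me3 signal and ratio per gene
#'
#' For each gene, counts mark fragments in the symmetric promoter window
#' (`tss +/- flank`, default 3 kb), normalizes each mark to counts per
#' million of its own library, and forms the pseudo-counted ratio
#' `(k4 + alpha) / (k27 + alpha)`. The pseudo-count keeps the ratio defined
#' and rank-stable when a window has no fragments for one mark. Flank and
#' alpha are recorded on the table and in every export.
#'
#' @param k4 [FragmentSet-class] for H3K4me3.
#' @param k27 [FragmentSet-class] for H3K27me3; must share the genotype of
#'   `k4`.
#' @param genes gene annotation `data.frame` ([readGeneTable()] schema).
#' @param flank promoter window half-width in bp (default 3000).
#' @param alpha pseudo-count in CPM units added to both marks (default 1).
#' @return a [BivalencyTable-class] (class column unset until
#'   [classifyPromoters()] is applied).
#' @export
promoterSignal <- function(k4, k27, genes, flank = 3000L, alpha = 1) {
  stopifnot(is(k4, "FragmentSet"), is(k27, "FragmentSet"))
  if (genotypeOf(k4) != genotypeOf(k27))
    stop("genotype mismatch between marks: ", genotypeOf(k4), " vs ",
         genotypeOf(k27))
  if (!nrow(genes)) stop("genes must be non-empty")
  win <- tssWindows(genes, flank)
  c4 <- windowCounts(k4, win)
  c27 <- windowCounts(k27, win)
  s4 <- cpmNormalize(c4, length(intervals(k4)))
  s27 <- cpmNormalize(c27, length(intervals(k27)))
  ratio <- (s4 + alpha) / (s27 + alpha)
  rec <- data.frame(gene_id = genes$gene_id, k4_signal = s4,
                    k27_signal = s27, ratio = ratio,
                    log2_ratio = log2(ratio), class = NA_character_,
                    relative_ratio = NA_real_, stringsAsFactors = FALSE)
  new("BivalencyTable", genotype = genotypeOf(k4),
      flank = as.integer(flank), alpha = alpha, records = rec)
}

#' Average per-replicate bivalency tables
#'
#' Combines replicate tables for the same genotype by averaging per-gene mark
#' signals and per-replicate ratios (mean of ratios, not ratio of means); the
#' log2 ratio is recomputed from the averaged ratio.
#'
#' @param tables list of [BivalencyTable-class] for the same genotype, gene
#'   universe, flank and alpha.
#' @return a single [BivalencyTable-class].
#' @export
averageBivalency <- function(tables) {
  stopifnot(length(tables) >= 1L)
  t1 <- tables[[1L]]
  for (t in tables[-1L]) {
    if (!identical(bivalencyRecords(t)$gene_id, bivalencyRecords(t1)$gene_id))
      stop("gene-universe mismatch across replicate tables")
    if (t@flank != t1@flank || t@alpha != t1@alpha ||
        t@genotype != t1@genotype)
      stop("replicate tables must share genotype, flank and alpha")
  }
  recs <- lapply(tables, bivalencyRecords)
  mcol <- function(col) rowMeans(do.call(cbind, lapply(recs, `[[`, col)))
  rec <- recs[[1L]]
  rec$k4_signal <- mcol("k4_signal")
  rec$k27_signal <- mcol("k27_signal")
  rec$ratio <- mcol("ratio")
  rec$log2_ratio <- log2(rec$ratio)
  new("BivalencyTable", genotype = t1@genotype, flank = t1@flank,
      alpha = t1@alpha, records = rec)
}

#' Classify promoters into the three-category scheme
#'
#' Both marks above their thresholds gives `bivalent`; exactly one gives
#' `K4_only` or `K27_only`; neither gives `neither`. Thresholds are in CPM
#' units (see [backgroundCpmThreshold()] for a data-driven default).
#'
#' @param table a [BivalencyTable-class].
#' @param k4Threshold,k27Threshold CPM enrichment thresholds (> 0).
#' @return the table with the `class` column filled.
#' @export
classifyPromoters <- function(table, k4Threshold, k27Threshold) {
  stopifnot(is(table, "BivalencyTable"))
  .assertScalarNum(k4Threshold, "k4Threshold")
  .assertScalarNum(k27Threshold, "k27Threshold")
  rec <- bivalencyRecords(table)
  hi4 <- rec$k4_signal > k4Threshold
  hi27 <- rec$k27_signal > k27Threshold
  rec$class <- ifelse(hi4 & hi27, "bivalent",
               ifelse(hi4, "K4_only",
               ifelse(hi27, "K27_only", "neither")))
  methods::initialize(table, records = rec)
}

#' Background-window CPM threshold for promoter classification
#'
#' Samples random windows away from any promoter window, computes their CPM,
#' and returns the requested quantile (default the 95th percentile); used as
#' the default mark-enrichment cutoff because no universal CPM threshold
#' exists.
#'
#' @param frags a [FragmentSet-class] for the mark.
#' @param genes gene annotation (promoter windows are avoided).
#' @param chromLengths named chromosome lengths (defaults to the fragment
#'   `seqlengths`).
#' @param flank window half-width, matching the promoter analysis.
#' @param n number of background windows to sample.
#' @param probs quantile to report.
#' @param seed random seed for the window sample.
#' @return CPM threshold (numeric scalar).
#' @export
backgroundCpmThreshold <- function(frags, genes, chromLengths = NULL,
                                   flank = 3000L, n = 500L, probs = 0.95,
                                   seed = 1L) {
  stopifnot(is(frags, "FragmentSet"))
  gr <- intervals(frags)
  if (is.null(chromLengths)) {
    chromLengths <- seqlengths(gr)
    if (any(is.na(chromLengths)))
      stop("chromosome lengths unknown; supply 'chromLengths'")
  }
  set.seed(.stageSeed(seed, "background-windows"))
  prom <- tssWindows(genes, flank)
  got <- GRanges()
  tries <- 0L
  while (length(got) < n && tries < 50L) {
    m <- n * 2L
    chr <- sample(names(chromLengths), m, replace = TRUE,
                  prob = chromLengths / sum(chromLengths))
    s <- .runifInt(m, 1L, as.integer(chromLengths[chr] - 2L * flank))
    cand <- GRanges(chr, IRanges(s, width = 2L * flank))
    cand <- cand[!overlapsAny(cand, prom, ignore.strand = TRUE)]
    got <- c(got, cand)
    tries <- tries + 1L
  }
  if (length(got) < n)
    stop("could not sample ", n, " non-promoter background windows")
  got <- got[seq_len(n)]
  cnt <- countOverlaps(got, gr, ignore.strand = TRUE)
  as.numeric(stats::quantile(cpmNormalize(cnt, length(gr)), probs = probs))
}

#' Knockout-relative promoter ratio per gene
#'
#' Per gene, the knockout ratio divided by the control ratio; 1 means no
#' change. Both tables must cover the same gene universe with the same flank
#' and pseudo-count.
#'
#' @param koTable [BivalencyTable-class] for the knockout.
#' @param wtTable [BivalencyTable-class] for the control.
#' @return the knockout table with `relative_ratio` filled.
#' @export
relativeRatio <- function(koTable, wtTable) {
  stopifnot(is(koTable, "BivalencyTable"), is(wtTable, "BivalencyTable"))
  ko <- bivalencyRecords(koTable)
  wt <- bivalencyRecords(wtTable)
  if (!identical(sort(ko$gene_id), sort(wt$gene_id)))
    stop("gene-universe mismatch between the two tables")
  if (koTable@flank != wtTable@flank || koTable@alpha != wtTable@alpha)
    stop("tables must share flank and alpha")
  ko$relative_ratio <- ko$ratio / wt$ratio[match(ko$gene_id, wt$gene_id)]
  methods::initialize(koTable, records = ko)
}

#' Rank genes by knockout-relative ratio change
#'
#' Genes sorted by descending relative ratio; ties broken by gene id for
#' determinism.
#'
#' @inheritParams relativeRatio
#' @return `data.frame` (`gene_id`, `relative_ratio`) in ranked order.
#' @export
rankGenesByRatioChange <- function(koTable, wtTable) {
  rr <- bivalencyRecords(relativeRatio(koTable, wtTable))
  out <- rr[order(-rr$relative_ratio, rr$gene_id),
            c("gene_id", "relative_ratio")]
  rownames(out) <- NULL
  out
}

#' Sliding-window Spearman correlation of ratio with expression
#'
#' Genes are ordered by expression (ties broken by input order), both series
#' are averaged within a sliding window (default 100 observations wide,
#' advancing by 1), and the Spearman rank correlation of the two
#' windowed-mean series is returned (ties mid-ranked).
#'
#' @param ratios per-gene ratio values.
#' @param expression per-gene expression values, same length and order.
#' @param window window width in observations (default 100).
#' @param step window increment (default 1).
#' @return list with `rho` and `nWindows`.
#' @export
slidingWindowSpearman <- function(ratios, expression, window = 100L,
                                  step = 1L) {
  if (length(ratios) != length(expression))
    stop("ratios and expression must be paired (same length)")
  if (any(!is.finite(ratios)) || any(!is.finite(expression)))
    stop("ratios and expression must be finite")
  n <- length(ratios)
  if (n < window)
    stop("fewer observations (", n, ") than the window width (", window,
         "); use a smaller window")
  ord <- order(expression)
  wr <- .windowMeans(ratios[ord], window, step)
  we <- .windowMeans(expression[ord], window, step)
  rho <- stats::cor(wr, we, method = "spearman")
  list(rho = rho, nWindows = length(wr))
}

#' Mark-enrichment difference between gene sets
#'
#' Two-sided test comparing a statistic (e.g. per-gene relative ratio)
#' between two gene sets; Mann-Whitney (Wilcoxon rank-sum) by default for
#' robustness at small replicate numbers, Welch t-test behind the flag.
#'
#' @param x,y numeric values for the two gene sets.
#' @param method `"wilcoxon"` (default) or `"t"`.
#' @return the `htest` object.
#' @export
geneSetRatioTest <- function(x, y, method = c("wilcoxon", "t")) {
  method <- match.arg(method)
  if (method == "wilcoxon") stats::wilcox.test(x, y, exact = FALSE)
  else stats::t.test(x, y)
}

#' Export a BivalencyTable as TSV
#'
#' Writes the per-gene records preceded by header comment lines recording
#' genotype, flank and pseudo-count.
#'
#' @param table a [BivalencyTable-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeBivalencyTable <- function(table, path) {
  stopifnot(is(table, "BivalencyTable"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# genotype=%s flank=%d alpha=%g", table@genotype,
                     table@flank, table@alpha), con)
  utils::write.table(bivalencyRecords(table), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a BivalencyTable written by [writeBivalencyTable()]
#' @param path path to the TSV.
#' @return a [BivalencyTable-class].
#' @export
readBivalencyTable <- function(path) {
  hdr <- readLines(path, n = 1L)
  m <- regmatches(hdr, regexec(
    "genotype=(\\S+) flank=(\\d+) alpha=([0-9.eE+-]+)", hdr))[[1L]]
  if (length(m) != 4L) stop("missing bivalency header line in ", path)
  rec <- utils::read.table(path, header = TRUE, sep = "\t", skip = 1L,
                           stringsAsFactors = FALSE)
  rec$class <- as.character(rec$class)
  new("BivalencyTable", genotype = m[2L], flank = as.integer(m[3L]),
      alpha = as.numeric(m[4L]), records = rec)
}
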