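#' Read a BED file into a PeakSet
#'
#' Reads BED3/BED6 (0-based half-open on disk) into a sorted [PeakSet-class]
#' whose intervals are a 1-based `GRanges`. Strand is taken from column 6 when
#' present, otherwise `"*"`. Malformed lines (non-integer coordinates, end not
#' greater than start) raise an error naming the offending line.
#'
#' @param path path to a BED file.
#' @param name label for the resulting peak set.
#' @param replicateId optional replicate label.
#' @return A [PeakSet-class]; empty file gives an empty set.
#' @examples
#' tf <- tempfile(fileext = ".bed")
#' writeLines(c("chr1\t100\t200", "chr1\t150\t300"), tf)
#' readBed(tf, name = "demo")
#' @export
readBed <- function(path, name = basename(path), replicateId = NA_character_) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(PeakSet(GRanges(), name = name, replicateId = replicateId))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop("BED parse error at line ", which(nf < 3L)[1L],
         ": fewer than 3 tab-separated columns")
  chrom <- vapply(fields, `[[`, "", 1L)
  s <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  e <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(s) | is.na(e))
  if (length(bad))
    stop("BED parse error at line ", bad[1L], ": non-integer coordinates")
  bad <- which(e <= s | s < 0L)
  if (length(bad))
    stop("BED parse error at line ", bad[1L],
         ": end must be > start and start >= 0")
  str <- rep("*", length(lines))
  has6 <- nf >= 6L
  if (any(has6)) {
    s6 <- vapply(fields[has6], `[[`, "", 6L)
    s6[!s6 %in% c("+", "-")] <- "*"
    str[has6] <- s6
  }
  gr <- GRanges(chrom, IRanges(s + 1L, e), strand = str)
  PeakSet(gr, name = name, replicateId = replicateId)
}

#' Write a PeakSet (or GRanges) to a BED file
#'
#' Writes BED6 when any interval is stranded, else BED3; 0-based half-open on
#' disk. `readBed(writeBed(x))` reproduces `x`'s intervals exactly.
#'
#' @param peaks a [PeakSet-class] or `GRanges`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeBed <- function(peaks, path) {
  gr <- if (is(peaks, "PeakSet")) intervals(peaks) else peaks
  if (!length(gr)) {
    file.create(path)
    return(invisible(path))
  }
  str <- as.character(strand(gr))
  lines <- if (all(str == "*")) {
    paste(as.character(seqnames(gr)), start(gr) - 1L, end(gr), sep = "\t")
  } else {
    paste(as.character(seqnames(gr)), start(gr) - 1L, end(gr), ".", 0L,
          ifelse(str == "*", ".", str), sep = "\t")
  }
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) stop("cannot write ", path, ": ",
                                          conditionMessage(e)))
  invisible(path)
}

#' Symmetric promoter window around a TSS
#'
#' The window spans `flank` bp on each side of the TSS in genomic coordinates,
#' regardless of strand (strand is retained on the output); the window is
#' clipped at the chromosome start. `tss` is 1-based; the returned `GRanges`
#' covers `[tss - flank, tss + flank)` in 0-based half-open terms, i.e. width
#' `2 * flank` when unclipped.
#'
#' @param genes `data.frame` with columns `gene_id`, `chrom`, `tss`, `strand`
#'   (as produced by [readGeneTable()] or [simulateAnnotation()]).
#' @param flank half-width in bp (> 0).
#' @return `GRanges` named by `gene_id`.
#' @examples
#' g <- data.frame(gene_id = "g1", chrom = "chr1", tss = 10001,
#'                 strand = "+", length = 2000)
#' tssWindows(g, 3000)  # 7001-13000, i.e. [7000,13000) in BED terms
#' @export
tssWindows <- function(genes, flank = 3000) {
  .assertScalarNum(flank, "flank")
  s <- pmax(genes$tss - flank, 1)
  e <- genes$tss + flank - 1
  gr <- GRanges(genes$chrom, IRanges(s, e), strand = genes$strand)
  names(gr) <- genes$gene_id
  gr
}

#' Read a gene annotation table
#'
#' Tab-separated with a header; required columns `gene_id`, `chrom`, `tss`
#' (1-based), `strand`, `length` (exonic length in bp, used for RPKM).
#'
#' @param path path to the TSV.
#' @return `data.frame`, one row per gene.
#' @export
readGeneTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  req <- c("gene_id", "chrom", "tss", "strand", "length")
  miss <- setdiff(req, names(tab))
  if (length(miss))
    stop("gene table schema error: missing column(s) ",
         paste(miss, collapse = ", "))
  if (anyDuplicated(tab$gene_id))
    stop("gene table uniqueness error: duplicated gene_id ",
         tab$gene_id[duplicated(tab$gene_id)][1L])
  if (any(tab$length <= 0)) stop("gene length must be > 0")
  tab[req]
}

#' Write a gene annotation table
#' @param genes `data.frame` with the [readGeneTable()] schema.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGeneTable <- function(genes, path) {
  req <- c("gene_id", "chrom", "tss", "strand", "length")
  utils::write.table(genes[req], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
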