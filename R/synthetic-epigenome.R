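#' Configuration for the synthetic epigenome generator
#'
#' Bundles every parameter of the simulated study: a toy genome, promoters in
#' four chromatin states, a knockout genotype that gains H3K4me3 and
#' accessibility at a designated responsive ("PrE-like") subset of bivalent
#' genes, three partially co-binding factors, ATAC fragment-size mixtures
#' carrying nucleosome information, and an expression model whose mean tracks
#' the promoter K4/K27 ratio.
#'
#' Defaults describe a desk-scale epigenome (2 chromosomes x 5 Mb, 500 genes,
#' 50 responsive, 2e5 fragments per sample, 3 replicates per genotype) on
#' which the full pipeline runs in minutes.
#'
#' @param nChroms number of chromosomes.
#' @param chromLength chromosome length in bp.
#' @param nGenes number of genes.
#' @param stateFractions named fractions for promoter states
#'   `k4_only`, `k27_only`, `bivalent`, `neither`; must sum to 1.
#' @param nResponsive number of knockout-responsive genes, drawn from the
#'   bivalent genes.
#' @param koK4Fold multiplicative H3K4me3 gain at responsive promoters in the
#'   knockout.
#' @param koAtacFold accessibility (ATAC sampling-rate) gain at responsive
#'   promoters and their enhancers in the knockout.
#' @param koExprLog2Fold log2 expression shift of responsive genes in the
#'   knockout.
#' @param enhancerPerGene enhancers placed per gene (10-50 kb from the TSS).
#' @param factorCombProbs named probabilities over the 8 factor-membership
#'   combinations (`none`, `A`, `B`, `C`, `AB`, `AC`, `BC`, `ABC`); sum to 1.
#' @param factorPeakHalfWidth half-width (bp) of a true factor binding window.
#' @param chipFragmentSizeRange ChIP fragment size range in bp (sonication
#'   scale).
#' @param chipEnrichmentFraction fraction of ChIP fragments falling in true
#'   windows (FRiP-like); the rest is uniform background.
#' @param atacSizeMixture list with `weights` (named `subnucleosomal`,
#'   `mononucleosomal`, summing to 1), `subRange` and `monoRange` size bands
#'   in bp.
#' @param atacBackgroundFraction fraction of each ATAC size component placed
#'   uniformly on the genome rather than at accessible loci/dyads.
#' @param depth expected fragments per sample.
#' @param nReplicates replicates per genotype.
#' @param expression list with `baseMean`, `linkCoef` (slope of log2 mean on
#'   the true promoter log2 K4/K27 ratio) and negative-binomial `dispersion`.
#' @param seed base random seed; every generator derives per-stage seeds from
#'   it and is bit-reproducible.
#' @return a validated `SimulationConfig` (named list).
#' @examples
#' cfg <- simulationConfig(nGenes = 50, nResponsive = 5, depth = 1e4)
#' @export
simulationConfig <- function(
    nChroms = 2L,
    chromLength = 5e6,
    nGenes = 500L,
    stateFractions = c(k4_only = 0.35, k27_only = 0.15,
                       bivalent = 0.40, neither = 0.10),
    nResponsive = 50L,
    koK4Fold = 3,
    koAtacFold = 4,
    koExprLog2Fold = 2,
    enhancerPerGene = 1L,
    factorCombProbs = c(none = 0.20, A = 0.08, B = 0.10, C = 0.10,
                        AB = 0.12, AC = 0.05, BC = 0.10, ABC = 0.25),
    factorPeakHalfWidth = 500L,
    chipFragmentSizeRange = c(200L, 500L),
    chipEnrichmentFraction = 0.3,
    atacSizeMixture = list(
      weights = c(subnucleosomal = 0.55, mononucleosomal = 0.45),
      subRange = c(30L, 99L), monoRange = c(180L, 247L)),
    atacBackgroundFraction = 0.3,
    depth = 2e5,
    nReplicates = 3L,
    expression = list(baseMean = 100, linkCoef = 0.5, dispersion = 0.1),
    seed = 1L) {
  cfg <- list(nChroms = as.integer(nChroms), chromLength = chromLength,
              nGenes = as.integer(nGenes), stateFractions = stateFractions,
              nResponsive = as.integer(nResponsive), koK4Fold = koK4Fold,
              koAtacFold = koAtacFold, koExprLog2Fold = koExprLog2Fold,
              enhancerPerGene = as.integer(enhancerPerGene),
              factorCombProbs = factorCombProbs,
              factorPeakHalfWidth = as.integer(factorPeakHalfWidth),
              chipFragmentSizeRange = as.integer(chipFragmentSizeRange),
              chipEnrichmentFraction = chipEnrichmentFraction,
              atacSizeMixture = atacSizeMixture,
              atacBackgroundFraction = atacBackgroundFraction,
              depth = depth, nReplicates = as.integer(nReplicates),
              expression = expression, seed = as.integer(seed))
  validateSimulationConfig(cfg)
}

#' Validate a simulation configuration
#' @param cfg a list of [simulationConfig()] fields.
#' @return the config with class `SimulationConfig`, or an error.
#' @export
validateSimulationConfig <- function(cfg) {
  sf <- cfg$stateFractions
  req <- c("k4_only", "k27_only", "bivalent", "neither")
  if (!all(req %in% names(sf)))
    stop("stateFractions must be named ", paste(req, collapse = ", "))
  if (abs(sum(sf) - 1) > 1e-8) stop("stateFractions must sum to 1")
  if (any(sf < 0)) stop("stateFractions must be >= 0")
  fc <- cfg$factorCombProbs
  reqc <- c("none", "A", "B", "C", "AB", "AC", "BC", "ABC")
  if (!all(reqc %in% names(fc)))
    stop("factorCombProbs must be named ", paste(reqc, collapse = ", "))
  if (abs(sum(fc) - 1) > 1e-8) stop("factorCombProbs must sum to 1")
  w <- cfg$atacSizeMixture$weights
  if (abs(sum(w) - 1) > 1e-8)
    stop("atac size mixture weights must sum to 1")
  for (nm in c("nChroms", "chromLength", "nGenes", "koK4Fold", "koAtacFold",
               "depth", "nReplicates", "chipEnrichmentFraction"))
    .assertScalarNum(cfg[[nm]], nm)
  if (cfg$chipEnrichmentFraction >= 1)
    stop("chipEnrichmentFraction must be in (0,1)")
  if (cfg$expression$dispersion <= 0)
    stop("expression dispersion must be > 0")
  structure(cfg, class = "SimulationConfig")
}

.chromNames <- function(cfg) paste0("chr", seq_len(cfg$nChroms))

.seqlengths <- function(cfg) {
  stats::setNames(rep(as.integer(cfg$chromLength), cfg$nChroms),
                  .chromNames(cfg))
}

#' Simulate a toy gene annotation with ground-truth chromatin states
#'
#' Places non-overlapping genes on the toy genome (TSS spacing at least twice
#' the largest analysis flank), draws a promoter state per gene with the
#' configured fractions, designates the responsive subset among bivalent
#' genes, assigns factor-membership triples, nucleosome dyads flanking each
#' TSS, and one or more enhancers 10-50 kb away. Realized per-gene mark
#' intensities carry log-normal gene-to-gene variation so ratios are
#' continuous.
#'
#' @param cfg a [simulationConfig()].
#' @return list with `genes` (annotation `data.frame`) and `truth`
#'   ([SyntheticTruth-class]). Identical seed gives bit-identical output.
#' @export
simulateAnnotation <- function(cfg) {
  cfg <- validateSimulationConfig(cfg)
  set.seed(.stageSeed(cfg$seed, "annotation"))
  chroms <- .chromNames(cfg)
  perChrom <- rep(cfg$nGenes %/% cfg$nChroms, cfg$nChroms)
  extra <- cfg$nGenes - sum(perChrom)
  if (extra > 0) perChrom[seq_len(extra)] <- perChrom[seq_len(extra)] + 1L
  margin <- 60000
  maxFlank <- 4000
  spacing <- floor((cfg$chromLength - 2 * margin) / max(perChrom))
  if (spacing < 3 * maxFlank)
    stop("capacity error: genome too small to place ", cfg$nGenes,
         " genes with non-overlapping analysis windows")
  jitter <- floor(spacing / 8)

  chrom <- rep(chroms, perChrom)
  idx <- unlist(lapply(perChrom, seq_len))
  tss <- margin + (idx - 0.5) * spacing +
    .runifInt(cfg$nGenes, -jitter, jitter)
  tss <- as.numeric(round(tss))
  strand <- sample(c("+", "-"), cfg$nGenes, replace = TRUE)
  glen <- .runifInt(cfg$nGenes, 500L, 5000L)
  gene_id <- sprintf("gene%04d", seq_len(cfg$nGenes))

  state <- sample(names(cfg$stateFractions), cfg$nGenes, replace = TRUE,
                  prob = cfg$stateFractions)
  bivalent <- which(state == "bivalent")
  if (cfg$nResponsive > length(bivalent))
    stop("nResponsive (", cfg$nResponsive,
         ") exceeds the number of bivalent genes (", length(bivalent), ")")
  responsive <- rep(FALSE, cfg$nGenes)
  responsive[sample(bivalent, cfg$nResponsive)] <- TRUE

  lnoise <- function(n) exp(stats::rnorm(n, 0, 0.25))
  k4_wt <- ifelse(state %in% c("k4_only", "bivalent"), 1, 0) *
    lnoise(cfg$nGenes)
  k27_wt <- ifelse(state %in% c("k27_only", "bivalent"), 1, 0) *
    lnoise(cfg$nGenes)
  k4_ko <- k4_wt * ifelse(responsive, cfg$koK4Fold, 1)
  k27_ko <- k27_wt
  accessBase <- c(k4_only = 1, bivalent = 0.6, k27_only = 0.15,
                  neither = 0.15)[state]
  atac_wt <- as.numeric(accessBase) * lnoise(cfg$nGenes)
  atac_ko <- atac_wt * ifelse(responsive, cfg$koAtacFold, 1)

  comb <- sample(names(cfg$factorCombProbs), cfg$nGenes, replace = TRUE,
                 prob = cfg$factorCombProbs)
  factorA <- grepl("A", comb)
  factorB <- grepl("B", comb)
  factorC <- grepl("C", comb)

  genes <- data.frame(gene_id = gene_id, chrom = chrom, tss = tss,
                      strand = strand, length = glen,
                      stringsAsFactors = FALSE)

  sl <- .seqlengths(cfg)
  hw <- cfg$factorPeakHalfWidth
  mkPeaks <- function(bound) {
    gr <- GRanges(chrom[bound],
                  IRanges(pmax(tss[bound] - hw, 1), tss[bound] + hw - 1),
                  seqlengths = sl)
    names(gr) <- gene_id[bound]
    sort(gr)
  }
  factorPeaks <- GRangesList(factorA = mkPeaks(factorA),
                             factorB = mkPeaks(factorB),
                             factorC = mkPeaks(factorC))

  dyadOff <- c(-400, -200, 200, 400)
  dy <- rep(tss, each = length(dyadOff)) + rep(dyadOff, times = cfg$nGenes)
  dyads <- GRanges(rep(chrom, each = length(dyadOff)), IRanges(dy, width = 1),
                   seqlengths = sl)
  mcols(dyads)$gene_id <- rep(gene_id, each = length(dyadOff))

  nEnh <- cfg$enhancerPerGene
  eg <- rep(seq_len(cfg$nGenes), each = nEnh)
  off <- .runifInt(length(eg), 10000L, 50000L) *
    sample(c(-1L, 1L), length(eg), replace = TRUE)
  ec <- pmin(pmax(tss[eg] + off, 5000), cfg$chromLength - 5000)
  enhancers <- GRanges(chrom[eg], IRanges(ec - 500, ec + 499),
                       seqlengths = sl)
  mcols(enhancers)$gene_id <- gene_id[eg]
  mcols(enhancers)$state <- ifelse(state[eg] == "k4_only", "active", "poised")
  enhW <- c(active = 0.8, poised = 0.4)[mcols(enhancers)$state]
  mcols(enhancers)$access_wt <- as.numeric(enhW)
  mcols(enhancers)$access_ko <- as.numeric(enhW) *
    ifelse(responsive[eg], cfg$koAtacFold, 1)

  gt <- cbind(genes,
              data.frame(state = state, responsive = responsive,
                         k4_wt = k4_wt, k27_wt = k27_wt,
                         k4_ko = k4_ko, k27_ko = k27_ko,
                         atac_wt = atac_wt, atac_ko = atac_ko,
                         factorA = factorA, factorB = factorB,
                         factorC = factorC, stringsAsFactors = FALSE))
  truth <- new("SyntheticTruth", genes = gt, factorPeaks = factorPeaks,
               dyads = dyads, enhancers = enhancers, config = unclass(cfg))
  list(genes = genes, truth = truth)
}

# windows + per-genotype weights for one ChIP target
.chipTargets <- function(truth, mark, genotype) {
  g <- truth@genes
  cfg <- truth@config
  ko <- genotype == "knockout"
  switch(mark,
    H3K4me3 = {
      w <- tssWindows(g, 3000)
      list(windows = w, wt = g$k4_wt, geno = if (ko) g$k4_ko else g$k4_wt)
    },
    H3K27me3 = {
      w <- tssWindows(g, 3000)
      list(windows = w, wt = g$k27_wt, geno = if (ko) g$k27_ko else g$k27_wt)
    },
    factorA = ,
    factorB = ,
    factorC = {
      w <- truth@factorPeaks[[mark]]
      n <- length(w)
      list(windows = w, wt = rep(1, n), geno = rep(1, n))
    },
    H3K4me1 = {
      e <- truth@enhancers
      w <- GRanges(seqnames(e),
                   IRanges(pmax(start(e) - 500, 1), end(e) + 500),
                   seqlengths = seqlengths(e))
      n <- length(w)
      list(windows = w, wt = rep(1, n), geno = rep(1, n))
    },
    H3K27ac = {
      e <- truth@enhancers
      act <- as.numeric(mcols(e)$state == "active")
      list(windows = granges(e), wt = act, geno = act)
    },
    stop("unknown mark or factor label: ", mark))
}

# draw fragments at windows: counts per window, uniform centers, given sizes
.placeWindowFragments <- function(windows, counts, sizeLo, sizeHi, sl) {
  idx <- rep(seq_along(windows), counts)
  n <- length(idx)
  if (!n) return(GRanges(seqlengths = sl))
  centers <- start(windows)[idx] +
    floor(stats::runif(n) * width(windows)[idx])
  sizes <- .runifInt(n, sizeLo, sizeHi)
  chr <- as.character(seqnames(windows))[idx]
  maxLen <- sl[chr]
  s <- pmin(pmax(centers - sizes %/% 2, 1), maxLen - sizes + 1)
  GRanges(chr, IRanges(s, width = sizes), seqlengths = sl)
}

# uniform background fragments over the genome
.placeBackgroundFragments <- function(n, sizeLo, sizeHi, sl) {
  if (!n) return(GRanges(seqlengths = sl))
  chr <- sample(names(sl), n, replace = TRUE, prob = sl / sum(sl))
  sizes <- .runifInt(n, sizeLo, sizeHi)
  s <- .runifInt(n, 1L, as.integer(sl[chr] - sizes))
  GRanges(chr, IRanges(s, width = sizes), seqlengths = sl)
}

#' Simulate ChIP fragments for one mark/factor, genotype and replicate
#'
#' Two-component inhomogeneous Poisson model: a uniform genomic background
#' carrying `1 - chipEnrichmentFraction` of the expected depth, and true
#' windows receiving the rest in proportion to their ground-truth intensity.
#' Window rates are normalized against the control-genotype total, so the
#' knockout multiplies the H3K4me3 rate at responsive promoters by
#' `koK4Fold` exactly (window-count ratios recover the fold); total emitted
#' fragments equal the depth up to Poisson noise. Fragment sizes are uniform
#' over the configured sonication range.
#'
#' @param truth a [SyntheticTruth-class].
#' @param mark one of `H3K4me3`, `H3K27me3`, `factorA`, `factorB`, `factorC`,
#'   `H3K4me1`, `H3K27ac`.
#' @param genotype `"control"` or `"knockout"`.
#' @param depth expected fragment count (defaults to the config depth).
#' @param replicate replicate index (enters the derived seed).
#' @param seed base seed (defaults to the config seed).
#' @return a [FragmentSet-class].
#' @export
simulateChipFragments <- function(truth, mark, genotype,
                                  depth = truth@config$depth, replicate = 1L,
                                  seed = truth@config$seed) {
  stopifnot(is(truth, "SyntheticTruth"))
  if (!genotype %in% c("control", "knockout"))
    stop("unknown genotype label: ", genotype)
  .assertScalarNum(depth, "depth")
  cfg <- truth@config
  tg <- .chipTargets(truth, mark, genotype)
  set.seed(.stageSeed(seed, paste("chip", mark, genotype, replicate)))
  sl <- .seqlengths(cfg)
  ef <- cfg$chipEnrichmentFraction
  Wctrl <- sum(tg$wt)
  rates <- if (Wctrl > 0) depth * ef * tg$geno / Wctrl else rep(0, length(tg$geno))
  counts <- stats::rpois(length(rates), rates)
  szr <- cfg$chipFragmentSizeRange
  frWin <- .placeWindowFragments(tg$windows, counts, szr[1], szr[2], sl)
  nBg <- stats::rpois(1, depth * (1 - ef))
  frBg <- .placeBackgroundFragments(nBg, szr[1], szr[2], sl)
  gr <- c(frWin, frBg)
  FragmentSet(gr,
              sampleId = paste(mark, genotype, "rep", replicate, sep = "_"),
              genotype = genotype, assay = paste0("chip:", mark))
}

#' Simulate ATAC fragments for one genotype and replicate
#'
#' Fragment sizes follow the configured sub-nucleosomal / mono-nucleosomal
#' mixture. Sub-nucleosomal fragments sample accessible loci (promoter
#' nucleosome-depleted regions and enhancer centers, +/-150 bp) over a uniform
#' background; mono-nucleosomal fragments center on true dyads with 20 bp
#' Gaussian jitter. In the knockout, the sampling rate of both components at
#' responsive promoters, their enhancers and their dyads is multiplied by
#' `koAtacFold`, so window fragment-count ratios recover the fold while the
#' overall size mixture is preserved.
#'
#' @inheritParams simulateChipFragments
#' @return a [FragmentSet-class].
#' @export
simulateAtacFragments <- function(truth, genotype,
                                  depth = truth@config$depth, replicate = 1L,
                                  seed = truth@config$seed) {
  stopifnot(is(truth, "SyntheticTruth"))
  if (!genotype %in% c("control", "knockout"))
    stop("unknown genotype label: ", genotype)
  cfg <- truth@config
  mix <- cfg$atacSizeMixture
  if (abs(sum(mix$weights) - 1) > 1e-8)
    stop("atac size mixture weights must sum to 1")
  set.seed(.stageSeed(seed, paste("atac", genotype, replicate)))
  sl <- .seqlengths(cfg)
  g <- truth@genes
  ko <- genotype == "knockout"
  bf <- cfg$atacBackgroundFraction
  wSub <- mix$weights[["subnucleosomal"]]
  wMono <- mix$weights[["mononucleosomal"]]

  ndr <- GRanges(g$chrom, IRanges(g$tss - 150, g$tss + 149), seqlengths = sl)
  enh <- truth@enhancers
  ec <- (start(enh) + end(enh)) %/% 2
  enhNdr <- GRanges(seqnames(enh), IRanges(ec - 150, ec + 149),
                    seqlengths = sl)
  lociWin <- c(ndr, enhNdr)
  wt <- c(g$atac_wt, mcols(enh)$access_wt)
  geno <- if (ko) c(g$atac_ko, mcols(enh)$access_ko) else wt
  A <- sum(wt)
  subRates <- depth * wSub * (1 - bf) * geno / A
  subCounts <- stats::rpois(length(subRates), subRates)
  frSub <- .placeWindowFragments(lociWin, subCounts,
                                 mix$subRange[1], mix$subRange[2], sl)
  nSubBg <- stats::rpois(1, depth * wSub * bf)
  frSubBg <- .placeBackgroundFragments(nSubBg, mix$subRange[1],
                                       mix$subRange[2], sl)

  dy <- truth@dyads
  resp <- g$responsive[match(mcols(dy)$gene_id, g$gene_id)]
  dwt <- rep(1, length(dy))
  dgeno <- if (ko) ifelse(resp, cfg$koAtacFold, 1) else dwt
  D <- sum(dwt)
  monoRates <- depth * wMono * (1 - bf) * dgeno / D
  monoCounts <- stats::rpois(length(monoRates), monoRates)
  midIdx <- rep(seq_along(dy), monoCounts)
  nMono <- length(midIdx)
  frMono <- GRanges(seqlengths = sl)
  if (nMono) {
    mids <- start(dy)[midIdx] + round(stats::rnorm(nMono, 0, 20))
    sizes <- .runifInt(nMono, mix$monoRange[1], mix$monoRange[2])
    chr <- as.character(seqnames(dy))[midIdx]
    s <- pmin(pmax(mids - sizes %/% 2, 1), sl[chr] - sizes + 1)
    frMono <- GRanges(chr, IRanges(s, width = sizes), seqlengths = sl)
  }
  nMonoBg <- stats::rpois(1, depth * wMono * bf)
  frMonoBg <- .placeBackgroundFragments(nMonoBg, mix$monoRange[1],
                                        mix$monoRange[2], sl)
  gr <- c(frSub, frSubBg, frMono, frMonoBg)
  FragmentSet(gr,
              sampleId = paste("atac", genotype, "rep", replicate, sep = "_"),
              genotype = genotype, assay = "atac")
}

#' Simulate an expression count matrix
#'
#' Negative-binomial counts per gene and replicate. The log2 mean is linear in
#' the true control-genotype promoter log2 K4/K27 intensity ratio (slope
#' `linkCoef`); in the knockout, responsive genes shift their mean by
#' `koExprLog2Fold` log2 units.
#'
#' @param truth a [SyntheticTruth-class].
#' @param genotype `"control"` or `"knockout"`.
#' @param nReplicates number of replicate columns (>= 2).
#' @param seed base seed (defaults to the config seed).
#' @return integer matrix, genes x replicates, rownames = gene ids.
#' @export
simulateExpression <- function(truth, genotype,
                               nReplicates = truth@config$nReplicates,
                               seed = truth@config$seed) {
  stopifnot(is(truth, "SyntheticTruth"))
  if (!genotype %in% c("control", "knockout"))
    stop("unknown genotype label: ", genotype)
  if (nReplicates < 2) stop("nReplicates must be >= 2")
  cfg <- truth@config
  ex <- cfg$expression
  if (ex$dispersion <= 0) stop("expression dispersion must be > 0")
  set.seed(.stageSeed(seed, paste("expr", genotype)))
  g <- truth@genes
  log2ratio <- log2((g$k4_wt + 0.1) / (g$k27_wt + 0.1))
  mu <- ex$baseMean * 2^(ex$linkCoef * log2ratio)
  if (genotype == "knockout")
    mu <- mu * ifelse(g$responsive, 2^cfg$koExprLog2Fold, 1)
  m <- matrix(stats::rnbinom(nrow(g) * nReplicates,
                             mu = rep(mu, nReplicates),
                             size = 1 / ex$dispersion),
              nrow = nrow(g), ncol = nReplicates)
  dimnames(m) <- list(g$gene_id,
                      paste(genotype, "rep", seq_len(nReplicates), sep = "_"))
  m
}

#' Emit the ground-truth binding windows of one factor as a PeakSet
#'
#' The emitted intervals are exactly the truth's binding windows, so
#' co-occupancy statistics can be tested without the plumbing peak caller.
#'
#' @param truth a [SyntheticTruth-class].
#' @param factor one of `"factorA"`, `"factorB"`, `"factorC"`.
#' @return a [PeakSet-class].
#' @export
emitTruePeaks <- function(truth, factor) {
  stopifnot(is(truth, "SyntheticTruth"))
  if (!factor %in% names(truth@factorPeaks))
    stop("unknown factor label: ", factor)
  PeakSet(truth@factorPeaks[[factor]], name = factor)
}

#' Deterministic two-set overlap fixture with exact counts
#'
#' Builds two peak sets with prescribed sizes and an exact number of
#' one-to-one overlapping pairs (each shared peak of A overlaps exactly one
#' peak of B and vice versa). Useful for exercising Venn arithmetic against
#' printed worked examples.
#'
#' @param nA,nB set sizes.
#' @param nShared number of one-to-one overlapping pairs
#'   (`<= min(nA, nB)`).
#' @param names labels for the two sets.
#' @param chrom chromosome name used for the synthetic coordinates.
#' @return list of two [PeakSet-class] objects.
#' @examples
#' fx <- cobindingPairFixture(100, 120, 67)
#' vennPercents(intersectPair(fx[[1]], fx[[2]]))
#' @export
cobindingPairFixture <- function(nA, nB, nShared, names = c("A", "B"),
                                 chrom = "chrFix") {
  stopifnot(nShared <= min(nA, nB))
  step <- 1000L
  sharedStart <- (seq_len(nShared) - 1L) * step + 1L
  aOnlyN <- nA - nShared
  bOnlyN <- nB - nShared
  off1 <- nShared * step + 10000L
  aOnly <- off1 + (seq_len(aOnlyN) - 1L) * step
  off2 <- off1 + aOnlyN * step + 10000L
  bOnly <- off2 + (seq_len(bOnlyN) - 1L) * step
  grA <- GRanges(chrom, IRanges(c(sharedStart, aOnly), width = 200))
  grB <- GRanges(chrom, IRanges(c(sharedStart + 100L, bOnly), width = 200))
  list(PeakSet(grA, name = names[1]), PeakSet(grB, name = names[2]))
}

#' Deterministic three-set overlap fixture with exact union and triple counts
#'
#' Builds three peak sets whose merged union has exactly `nUnion` loci, of
#' which exactly `nTriple` are covered by all three sets; the remaining loci
#' are single-factor, assigned round-robin.
#'
#' @param nUnion merged union locus count.
#' @param nTriple number of loci co-bound by all three sets.
#' @param names labels for the three sets.
#' @param chrom chromosome name used for the synthetic coordinates.
#' @return list of three [PeakSet-class] objects.
#' @export
cobindingTripleFixture <- function(nUnion, nTriple,
                                   names = c("A", "B", "C"),
                                   chrom = "chrFix") {
  stopifnot(nTriple <= nUnion)
  step <- 1000L
  base <- (seq_len(nTriple) - 1L) * step
  a <- IRanges(base + 1L, width = 300)
  b <- IRanges(base + 101L, width = 300)
  c3 <- IRanges(base + 201L, width = 300)
  rem <- nUnion - nTriple
  who <- rep_len(1:3, rem)
  off <- nTriple * step + 10000L
  single <- IRanges(off + (seq_len(rem) - 1L) * step, width = 200)
  grA <- GRanges(chrom, c(a, single[who == 1L]))
  grB <- GRanges(chrom, c(b, single[who == 2L]))
  grC <- GRanges(chrom, c(c3, single[who == 3L]))
  list(PeakSet(grA, name = names[1]), PeakSet(grB, name = names[2]),
       PeakSet(grC, name = names[3]))
}
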