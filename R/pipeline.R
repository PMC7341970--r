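.pipelineDefaults <- function() {
  list(simulation = list(),
       flankPromoter = 3000L, flankClusters = 4000L, binSize = 10L,
       metaFlank = 2000L, window = 100L, step = 1L,
       fdr = 0.05, lfc = 1, minSupport = 2L, alpha = 1,
       seed = 1L, outDir = "epiquant_out")
}

#' Validate and normalize a pipeline configuration
#'
#' Accepts a named list or a YAML/JSON file path. Unknown keys (top-level or
#' inside the `simulation` block) are rejected exhaustively, defaults are
#' injected, and the resolved config is returned; validation is idempotent.
#' Defaults equal the analysis parameters used throughout the package:
#' promoter flank 3000, cluster flank 4000, bin 10, sliding window 100 step
#' 1, FDR 0.05, |log2FC| 1, replicate support 2.
#'
#' @param config named list, or path to a `.yaml`/`.yml`/`.json` file; an
#'   empty list or file yields the full default config.
#' @return the resolved config (class `PipelineConfig`).
#' @export
validateConfig <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
    if (is.null(config)) config <- list()
  }
  if (!is.list(config)) stop("config must be a named list or a file path")
  defaults <- .pipelineDefaults()
  errs <- character()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    errs <- c(errs, paste0("unknown key(s): ", paste(unknown, collapse = ", ")))
  simKnown <- names(formals(simulationConfig))
  if (!is.null(config$simulation)) {
    if (!is.list(config$simulation)) {
      errs <- c(errs, "'simulation' must be a named list")
    } else {
      simUnknown <- setdiff(names(config$simulation), simKnown)
      if (length(simUnknown))
        errs <- c(errs, paste0("unknown simulation key(s): ",
                               paste(simUnknown, collapse = ", ")))
    }
  }
  merged <- utils::modifyList(defaults, config[setdiff(names(config), unknown)])
  num <- c("flankPromoter", "flankClusters", "binSize", "metaFlank", "window",
           "step", "fdr", "lfc", "minSupport", "alpha", "seed")
  for (nm in num) {
    v <- merged[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      errs <- c(errs, paste0("'", nm, "' must be a finite numeric scalar"))
  }
  if (!is.character(merged$outDir) || length(merged$outDir) != 1L)
    errs <- c(errs, "'outDir' must be a single path")
  if (length(errs)) stop(paste(errs, collapse = "; "))
  for (nm in c("flankPromoter", "flankClusters", "binSize", "metaFlank",
               "window", "step", "minSupport", "seed"))
    merged[[nm]] <- as.integer(merged[[nm]])
  structure(merged, class = "PipelineConfig")
}

.stageRun <- function(stage, outDir, expr) {
  t0 <- Sys.time()
  res <- tryCatch(expr, error = function(e) {
    writeLines(paste("failed at stage:", stage),
               file.path(outDir, "FAILED"))
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  message(sprintf("[epiquant] stage %-14s %6.2fs", stage,
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  res
}

# consensus accessibility peak set over promoter and enhancer NDRs,
# plus the ids of the truth-responsive loci
.atacConsensus <- function(truth) {
  g <- truth@genes
  sl <- .seqlengths(validateSimulationConfig(truth@config))
  prom <- GRanges(g$chrom, IRanges(g$tss - 150, g$tss + 149), seqlengths = sl)
  names(prom) <- paste0(g$gene_id, "_prom")
  enh <- truth@enhancers
  ec <- (start(enh) + end(enh)) %/% 2L
  enhNdr <- GRanges(seqnames(enh), IRanges(ec - 150, ec + 149),
                    seqlengths = sl)
  names(enhNdr) <- paste0(mcols(enh)$gene_id, "_enh",
                          seq_along(enhNdr))
  loci <- c(prom, enhNdr)
  respGenes <- g$gene_id[g$responsive]
  respIds <- c(paste0(respGenes, "_prom"),
               names(enhNdr)[mcols(enh)$gene_id %in% respGenes])
  list(loci = loci, responsiveIds = respIds)
}

#' Run the full synthetic-epigenome analysis pipeline
#'
#' Simulates the configured epigenome, then runs every analysis stage:
#' per-replicate promoter bivalency tables averaged per genotype, promoter
#' classification against background-derived thresholds, knockout-relative
#' ratios with responsive-gene recovery metrics, factor co-occupancy (pair
#' and triple Venn, seven TSS clusters), differential ATAC accessibility with
#' dependent-peak classification and truth Jaccard, differential expression
#' with DEG recovery, the sliding-window ratio/expression Spearman, and a TSS
#' ATAC meta-profile. All stage outputs are persisted under `outDir` beside
#' the resolved config; the machine-readable report is returned and written
#' as JSON with a stable key order. Identical seed and config give an
#' identical report.
#'
#' @param config a [validateConfig()] input (list or file path).
#' @return the report, invisibly (a named list).
#' @export
runPipeline <- function(config = list()) {
  cfg <- validateConfig(config)
  outDir <- cfg$outDir
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  unlink(file.path(outDir, "FAILED"))
  jsonlite::write_json(unclass(cfg), file.path(outDir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  simArgs <- utils::modifyList(list(seed = cfg$seed), cfg$simulation)
  simCfg <- do.call(simulationConfig, simArgs)
  genos <- c("control", "knockout")
  nRep <- simCfg$nReplicates

  ann <- .stageRun("simulate", outDir, {
    a <- simulateAnnotation(simCfg)
    writeGeneTable(a$genes, file.path(outDir, "genes.tsv"))
    utils::write.table(truthGenes(a$truth), file.path(outDir, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    for (f in names(a$truth@factorPeaks))
      writeBed(a$truth@factorPeaks[[f]],
               file.path(outDir, paste0("peaks_", f, ".bed")))
    a
  })
  truth <- ann$truth
  genes <- ann$genes

  biv <- .stageRun("bivalency", outDir, {
    tabs <- list()
    for (geno in genos) {
      reps <- lapply(seq_len(nRep), function(r) {
        k4 <- simulateChipFragments(truth, "H3K4me3", geno, replicate = r)
        k27 <- simulateChipFragments(truth, "H3K27me3", geno, replicate = r)
        promoterSignal(k4, k27, genes, flank = cfg$flankPromoter,
                       alpha = cfg$alpha)
      })
      tabs[[geno]] <- averageBivalency(reps)
    }
    k4bg <- simulateChipFragments(truth, "H3K4me3", "control", replicate = 1L)
    k27bg <- simulateChipFragments(truth, "H3K27me3", "control",
                                   replicate = 1L)
    thr4 <- backgroundCpmThreshold(k4bg, genes, flank = cfg$flankPromoter,
                                   seed = cfg$seed)
    thr27 <- backgroundCpmThreshold(k27bg, genes, flank = cfg$flankPromoter,
                                    seed = cfg$seed)
    tabs <- lapply(tabs, classifyPromoters, k4Threshold = thr4,
                   k27Threshold = thr27)
    tabs$knockout <- relativeRatio(tabs$knockout, tabs$control)
    for (geno in genos)
      writeBivalencyTable(tabs[[geno]],
                          file.path(outDir, paste0("bivalency_", geno, ".tsv")))
    ranked <- rankGenesByRatioChange(tabs$knockout, tabs$control)
    utils::write.table(ranked, file.path(outDir, "ranked_genes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(tables = tabs, ranked = ranked,
         thresholds = c(k4 = thr4, k27 = thr27))
  })

  recovery <- .stageRun("recovery", outDir, {
    rr <- biv$ranked
    thr <- stats::quantile(rr$relative_ratio, 0.9)
    pred <- rr$gene_id[rr$relative_ratio > thr]
    trueResp <- truthGenes(truth)$gene_id[truthGenes(truth)$responsive]
    tp <- length(intersect(pred, trueResp))
    list(sensitivity = tp / length(trueResp),
         precision = if (length(pred)) tp / length(pred) else 0,
         nPredicted = length(pred))
  })

  venn <- .stageRun("cooccupancy", outDir, {
    pk <- lapply(c("factorA", "factorB", "factorC"), emitTruePeaks,
                 truth = truth)
    pair <- intersectPair(pk[[1]], pk[[2]])
    triple <- intersectTriple(pk[[1]], pk[[2]], pk[[3]])
    writeVennResult(pair, file.path(outDir, "venn_pair.json"))
    writeVennResult(triple, file.path(outDir, "venn_triple.json"))
    clusters <- assignTssClusters(genes, pk[[1]], pk[[2]], pk[[3]],
                                  flank = cfg$flankClusters)
    utils::write.table(clusters, file.path(outDir, "clusters.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(pair = pair, triple = triple,
         clusterSizes = as.list(table(clusters$cluster)))
  })

  atac <- .stageRun("accessibility", outDir, {
    cons <- .atacConsensus(truth)
    frags <- lapply(genos, function(geno)
      lapply(seq_len(nRep), function(r)
        simulateAtacFragments(truth, geno, replicate = r)))
    names(frags) <- genos
    countMat <- function(fl) vapply(fl, windowCounts, windows = cons$loci,
                                    FUN.VALUE = integer(length(cons$loci)))
    cw <- countMat(frags$control); ck <- countMat(frags$knockout)
    diff <- diffAccessibility(cw, ck, peakIds = names(cons$loci),
                              fdr = cfg$fdr, lfc = cfg$lfc)
    writeDiffResult(diff, file.path(outDir, "atac_diff.tsv"))
    consSet <- PeakSet(cons$loci, name = "atac_consensus")
    o <- order(as.character(seqnames(cons$loci)), start(cons$loci))
    split <- classifyDependentPeaks(diff[o, ], consSet,
                                    direction = "increase")
    writeBed(split$dependent, file.path(outDir, "dependent_peaks.bed"))
    writeBed(split$independent, file.path(outDir, "independent_peaks.bed"))
    depIds <- diff$feature_id[diff$significant & diff$log2FC > 0]
    jac <- length(intersect(depIds, cons$responsiveIds)) /
      length(union(depIds, cons$responsiveIds))
    anchors <- GRanges(genes$chrom, IRanges(genes$tss, width = 1L),
                       strand = genes$strand)
    mp <- metaProfile(frags$control[[1]], anchors,
                      flank = cfg$metaFlank, binSize = cfg$binSize)
    writeMetaProfile(mp, file.path(outDir, "metaprofile_tss.tsv"))
    nb <- length(mp@values)
    list(nDependent = length(depIds),
         jaccard = jac,
         edgeBinMean = mean(c(mp@values[1:5], mp@values[(nb - 4):nb])))
  })

  expr <- .stageRun("expression", outDir, {
    mc <- simulateExpression(truth, "control")
    mk <- simulateExpression(truth, "knockout")
    deg <- callDeg(nbTest(mc, mk), fdr = cfg$fdr, lfc = cfg$lfc)
    writeDiffResult(deg, file.path(outDir, "deg.tsv"))
    trueResp <- truthGenes(truth)$gene_id[truthGenes(truth)$responsive]
    up <- attr(deg, "up")
    rec <- bivalencyRecords(biv$tables$control)
    sw <- slidingWindowSpearman(rec$ratio, rowMeans(mc),
                                window = cfg$window, step = cfg$step)
    list(nUp = length(up), nDown = length(attr(deg, "down")),
         nSignificant = sum(deg$significant),
         truePositives = length(intersect(up, trueResp)),
         falsePositives = length(setdiff(deg$feature_id[deg$significant],
                                         trueResp)),
         spearmanRho = sw$rho, nWindows = sw$nWindows)
  })

  promClasses <- as.list(table(factor(
    bivalencyRecords(biv$tables$control)$class,
    levels = c("K4_only", "K27_only", "bivalent", "neither"))))

  report <- list(
    seed = cfg$seed,
    nGenes = simCfg$nGenes,
    promoterClassCounts = promClasses,
    classThresholds = as.list(biv$thresholds),
    vennPair = list(percents = as.list(venn$pair@percents),
                    counts = as.list(venn$pair@overlapCounts)),
    vennTriple = list(percent = unname(venn$triple@percents["cobound"]),
                      unionSize = venn$triple@unionSize,
                      tripleCount = unname(
                        venn$triple@overlapCounts[["ABC"]])),
    clusterSizes = venn$clusterSizes,
    degCounts = list(up = expr$nUp, down = expr$nDown,
                     significant = expr$nSignificant),
    recovery = list(responsiveSensitivity = recovery$sensitivity,
                    responsivePrecision = recovery$precision,
                    atacDependentJaccard = atac$jaccard,
                    degTruePositives = expr$truePositives,
                    degFalsePositives = expr$falsePositives),
    spearmanRho = expr$spearmanRho,
    metaProfileEdgeBinMean = atac$edgeBinMean)
  jsonlite::write_json(report, file.path(outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
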