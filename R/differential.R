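#' Negative-binomial differential test for replicate count matrices
#'
#' The package's own documented count test, applied to both expression and
#' accessibility counts. Steps: (1) median-of-ratios size factors (each
#' sample's median count ratio to the per-feature geometric-mean reference),
#' which are robust to a minority of truly changing features where plain
#' total-count scaling would shift every null feature; samples with no
#' usable reference features fall back to total-count scaling; (2) per-group
#' normalized means; (3) a
#' single method-of-moments dispersion pooled across features (mean-weighted
#' over features with positive signal) with a floor of 0.01; (4) a two-sided
#' Wald-style statistic on the difference of log normalized means, with the
#' delta-method standard error `sqrt((1/m + phi)/n)` per group against a
#' standard-normal reference. Log2 fold changes use a pseudo-count of 0.5 on
#' normalized means, so all-zero features return `log2FC = 0`, `p = 1`.
#'
#' @param counts1 matrix features x replicates, group 1 (e.g. control).
#' @param counts2 matrix features x replicates, group 2 (e.g. knockout);
#'   log2FC is group 2 over group 1.
#' @param dispersionFloor lower bound for the pooled dispersion.
#' @return `data.frame`: `feature_id`, `baseMean1`, `baseMean2`, `log2FC`,
#'   `p_value`.
#' @export
nbTest <- function(counts1, counts2, dispersionFloor = 0.01) {
  counts1 <- as.matrix(counts1); counts2 <- as.matrix(counts2)
  if (ncol(counts1) < 2L || ncol(counts2) < 2L)
    stop("at least 2 replicates per group are required")
  if (nrow(counts1) != nrow(counts2))
    stop("count matrices must have the same features")
  all <- cbind(counts1, counts2)
  logGeo <- rowMeans(log(all))            # -Inf for any feature with a zero
  use <- is.finite(logGeo)
  if (sum(use) >= 10L) {
    sf <- apply(all[use, , drop = FALSE], 2L, function(k)
      exp(stats::median(log(k) - logGeo[use])))
  } else {
    sf <- colSums(all)
  }
  sf <- sf / mean(sf)
  sf[sf == 0 | !is.finite(sf)] <- 1
  n1 <- ncol(counts1); n2 <- ncol(counts2)
  norm1 <- sweep(counts1, 2, sf[seq_len(n1)], "/")
  norm2 <- sweep(counts2, 2, sf[n1 + seq_len(n2)], "/")
  m1 <- rowMeans(norm1); m2 <- rowMeans(norm2)

  # pooled method-of-moments dispersion: (s^2 - mu) / mu^2, weighted by mu
  momPhi <- function(nm, m) {
    v <- apply(nm, 1L, stats::var)
    keep <- m > 0
    num <- sum(pmax(v[keep] - m[keep], 0))
    den <- sum(m[keep]^2)
    c(num, den)
  }
  p1 <- momPhi(norm1, m1); p2 <- momPhi(norm2, m2)
  phi <- if ((p1[2] + p2[2]) > 0) (p1[1] + p2[1]) / (p1[2] + p2[2]) else 0
  phi <- max(phi, dispersionFloor)

  a1 <- m1 + 0.5; a2 <- m2 + 0.5
  log2FC <- log2(a2 / a1)
  se <- sqrt((1 / a1 + phi) / n1 + (1 / a2 + phi) / n2)
  z <- log(a2 / a1) / se
  p <- 2 * stats::pnorm(-abs(z))
  zero <- m1 == 0 & m2 == 0
  p[zero] <- 1
  log2FC[zero] <- 0
  ids <- rownames(counts1)
  if (is.null(ids)) ids <- sprintf("feature%05d", seq_len(nrow(counts1)))
  data.frame(feature_id = ids, baseMean1 = m1, baseMean2 = m2,
             log2FC = log2FC, p_value = p, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (via `stats::p.adjust`), monotone non-decreasing in
#' sorted order and capped at 1. Inputs outside `[0, 1]` raise an error.
#'
#' @param p vector of p-values in `[0, 1]`.
#' @return vector of q-values, same order as `p`.
#' @export
bhFdr <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("all p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Call differentially expressed / accessible features
#'
#' Applies the joint rule: significant when `q < fdr` and `|log2FC| > lfc`;
#' up means `log2FC > lfc`, down means `log2FC < -lfc`.
#'
#' @param results `data.frame` from [nbTest()]; a `q_value` column is added
#'   with [bhFdr()] if absent.
#' @param fdr FDR threshold (default 0.05).
#' @param lfc absolute log2 fold-change threshold (default 1).
#' @return the table with `q_value`, `significant` and `direction` columns;
#'   attributes `up` and `down` hold the split feature-id vectors.
#' @export
callDeg <- function(results, fdr = 0.05, lfc = 1) {
  if (!"q_value" %in% names(results))
    results$q_value <- bhFdr(results$p_value)
  results$significant <- results$q_value < fdr & abs(results$log2FC) > lfc
  results$direction <- ifelse(!results$significant, "ns",
                       ifelse(results$log2FC > 0, "up", "down"))
  attr(results, "up") <- results$feature_id[results$direction == "up"]
  attr(results, "down") <- results$feature_id[results$direction == "down"]
  results
}

#' Differential accessibility over a consensus peak set
#'
#' Applies [nbTest()] to per-peak replicate counts, adds BH q-values, and
#' flags significant changes with the same FDR/LFC rule as expression.
#'
#' @param countsWT,countsKO matrices peaks x replicates.
#' @param peakIds optional peak identifiers (defaults to rownames).
#' @param fdr,lfc thresholds (defaults 0.05 and 1).
#' @return `data.frame` as from [callDeg()].
#' @export
diffAccessibility <- function(countsWT, countsKO, peakIds = NULL,
                              fdr = 0.05, lfc = 1) {
  res <- nbTest(countsWT, countsKO)
  if (!is.null(peakIds)) res$feature_id <- peakIds
  callDeg(res, fdr = fdr, lfc = lfc)
}

#' Split a consensus peak set into factor-dependent and -independent peaks
#'
#' Dependent peaks are those with a significant change in the stated
#' direction (default: accessibility increase in the knockout); the remainder
#' are independent. The two sets partition the consensus set exactly.
#'
#' @param diff `data.frame` from [diffAccessibility()], one row per peak in
#'   the order of `peaks`.
#' @param peaks the consensus [PeakSet-class] the counts were taken over.
#' @param direction `"increase"` (in knockout/group 2) or `"decrease"`.
#' @return list with `dependent` and `independent` [PeakSet-class] objects.
#' @export
classifyDependentPeaks <- function(diff, peaks,
                                   direction = c("increase", "decrease")) {
  direction <- match.arg(direction)
  stopifnot(is(peaks, "PeakSet"), nrow(diff) == length(peaks))
  sel <- diff$significant &
    (if (direction == "increase") diff$log2FC > 0 else diff$log2FC < 0)
  gr <- intervals(peaks)
  list(dependent = PeakSet(gr[sel],
                           name = paste0(peaks@name, "_dependent")),
       independent = PeakSet(gr[!sel],
                             name = paste0(peaks@name, "_independent")))
}

#' Relative expression by the 2^-ddCt method
#'
#' `ddCt = (Ct_target,cond - Ct_ref,cond) - (Ct_target,ctrl - Ct_ref,ctrl)`;
#' fold change is `2^-ddCt`.
#'
#' @param ctTargetCond,ctRefCond,ctTargetCtrl,ctRefCtrl Ct values.
#' @return fold change(s), positive.
#' @export
ddctFoldChange <- function(ctTargetCond, ctRefCond, ctTargetCtrl, ctRefCtrl) {
  dd <- (ctTargetCond - ctRefCond) - (ctTargetCtrl - ctRefCtrl)
  2^(-dd)
}

#' ChIP-qPCR enrichment as percent of input
#'
#' Adjusts the input Ct for the input fraction
#' (`ct_input_adj = ct_input - log2(1/input_fraction)`) and reports
#' `100 * 2^(ct_input_adj - ct_ip)`.
#'
#' @param ctInput Ct of the input sample.
#' @param ctIp Ct of the immunoprecipitated sample.
#' @param inputFraction fraction of chromatin kept as input, in `(0, 1]`.
#' @return percent of input (>= 0).
#' @export
percentInput <- function(ctInput, ctIp, inputFraction) {
  if (any(inputFraction <= 0) || any(inputFraction > 1))
    stop("inputFraction must lie in (0, 1]")
  ctAdj <- ctInput - log2(1 / inputFraction)
  100 * 2^(ctAdj - ctIp)
}

#' Export a differential-result table as TSV
#' @param results `data.frame` from [callDeg()] / [diffAccessibility()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeDiffResult <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
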