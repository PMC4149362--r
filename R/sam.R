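# Significance Analysis of Microarrays. Per-gene relative difference
# d = (mean disease - mean control) / (s + s0) with gene-specific pooled
# scatter s and an exchangeability constant s0; significance is assessed
# against expected order statistics of d under group-label permutations,
# and the false discovery rate at a threshold delta is estimated as the
# median number of falsely called genes across permutations divided by
# the observed number of called genes.

.samScatter <- function(m, isControl) {
  n1 <- sum(isControl); n2 <- sum(!isControl)
  mc <- rowMeans(m[, isControl, drop = FALSE])
  md <- rowMeans(m[, !isControl, drop = FALSE])
  ssc <- rowSums((m[, isControl, drop = FALSE] - mc)^2)
  ssd <- rowSums((m[, !isControl, drop = FALSE] - md)^2)
  a <- (1 / n1 + 1 / n2) / (n1 + n2 - 2)
  list(r = md - mc, s = sqrt(a * (ssc + ssd)))
}

# Tusher-style s0: the percentile of the s distribution minimising the
# coefficient of variation of d across s-quantile windows.
.chooseS0 <- function(r, s, policy) {
  if (policy == "median") return(median(s))
  cand <- unique(quantile(s, seq(0, 1, by = 0.05), names = FALSE))
  windows <- cut(rank(s, ties.method = "first"),
                 breaks = max(2, min(10, floor(length(s) / 20))),
                 labels = FALSE)
  cv <- vapply(cand, function(s0) {
    d <- r / (s + s0)
    mads <- vapply(split(d, windows), mad, numeric(1))
    if (mean(mads) == 0) return(Inf)
    sd(mads) / mean(mads)
  }, numeric(1))
  cand[which.min(cv)]
}

# cut points for a given delta: walking the sorted d against expected
# order statistics, the first positive-side gene whose excess over the
# expected value reaches delta sets the upper cut (all larger d called),
# and symmetrically for the lower cut.
.samCuts <- function(dSorted, expected, delta) {
  diffs <- dSorted - expected
  upIdx <- which(diffs >= delta & dSorted > 0)
  loIdx <- which(diffs <= -delta & dSorted < 0)
  list(cutUp = if (length(upIdx)) dSorted[min(upIdx)] else Inf,
       cutLow = if (length(loIdx)) dSorted[max(loIdx)] else -Inf)
}

#' Significance Analysis of Microarrays
#'
#' Computes the SAM relative-difference statistic for every gene,
#' expected order statistics from balanced group-label permutations
#' (full enumeration when the number of distinct assignments does not
#' exceed `nPermutations`, otherwise seeded sampling without
#' replacement), and a delta/FDR calibration table. Genes with zero
#' scatter in both groups are excluded from calling and reported in the
#' result. The reported FDR column is the running minimum over the
#' ascending delta grid, so the estimate is non-increasing in delta.
#'
#' An optional fold-change filter requires the average disease/control
#' expression ratio (computed as 2^(mean difference) on the log2 scale)
#' to exceed `foldChange` for positive calls, or fall below
#' 1/`foldChange` for negative calls.
#'
#' @param dataset an [ExpressionDataset-class] with >= 2 samples per
#'   group.
#' @param nPermutations number of label permutations (>= 1).
#' @param s0Policy `"tusher"` (coefficient-of-variation minimising
#'   percentile of the s distribution) or `"median"` (median of s).
#' @param foldChange optional fold-change threshold (> 1), or `NULL`
#'   (default) for no filter.
#' @param seed integer seed for permutation sampling.
#' @param fdrTarget target FDR used to calibrate the reported delta via
#'   [selectDeSam()].
#' @return a [SamResult-class].
#' @export
samAnalysis <- function(dataset, nPermutations = 200,
                        s0Policy = c("tusher", "median"),
                        foldChange = NULL, seed = 1,
                        fdrTarget = 0.0019) {
  s0Policy <- match.arg(s0Policy)
  stopifnot(nPermutations >= 1)
  if (!is.null(foldChange) && foldChange <= 1)
    stop("foldChange must be > 1 (or NULL for no filter)")
  m <- exprsValues(dataset)
  grp <- sampleGroups(dataset)
  isControl <- grp == "control"
  n1 <- sum(isControl); n2 <- sum(!isControl)
  if (n1 < 2 || n2 < 2) stop("need at least 2 samples per group")

  obs <- .samScatter(m, isControl)
  excluded <- rownames(m)[obs$s == 0 & obs$r == 0]
  keep <- !(rownames(m) %in% excluded)
  if (length(excluded))
    message("excluded ", length(excluded),
            " gene(s) with zero scatter in both groups")
  mK <- m[keep, , drop = FALSE]
  obs <- .samScatter(mK, isControl)
  s0 <- .chooseS0(obs$r, obs$s, s0Policy)
  d <- obs$r / (obs$s + s0)
  names(d) <- rownames(mK)
  nGenes <- length(d)

  nTotal <- choose(n1 + n2, n1)
  perms <- if (nTotal <= nPermutations) {
    combn(n1 + n2, n1)
  } else {
    withSeed(seed, {
      seen <- new.env(hash = TRUE)
      out <- matrix(0L, n1, nPermutations)
      i <- 0
      while (i < nPermutations) {
        cand <- sort(sample.int(n1 + n2, n1))
        key <- paste(cand, collapse = ",")
        if (is.null(seen[[key]])) {
          seen[[key]] <- TRUE
          i <- i + 1
          out[, i] <- cand
        }
      }
      out
    })
  }
  permD <- apply(perms, 2, function(ctrlIdx) {
    lab <- seq_len(n1 + n2) %in% ctrlIdx
    p <- .samScatter(mK, lab)
    sort(p$r / (p$s + s0))
  })                                   # nGenes x nPerm, columns sorted
  expected <- rowMeans(permD)

  ordIdx <- order(d)
  dSorted <- d[ordIdx]
  # delta grid from the spread of observed-vs-expected differences
  maxDiff <- max(abs(dSorted - expected))
  deltaGrid <- unique(c(0, seq(0, maxDiff * 1.001, length.out = 101)))
  foldOk <- rep(TRUE, nGenes)
  if (!is.null(foldChange)) {
    ratio <- 2^(rowMeans(mK[, !isControl, drop = FALSE]) -
                  rowMeans(mK[, isControl, drop = FALSE]))
    foldOk <- ifelse(d > 0, ratio >= foldChange, ratio <= 1 / foldChange)
  }
  calledAt <- function(cuts) {
    names(d)[(d >= cuts$cutUp | d <= cuts$cutLow) & foldOk]
  }
  emptyNoted <- FALSE
  tab <- do.call(rbind, lapply(deltaGrid, function(delta) {
    cuts <- .samCuts(dSorted, expected, delta)
    called <- calledAt(cuts)
    false <- median(vapply(seq_len(ncol(permD)), function(j) {
      v <- permD[, j]
      sum(v >= cuts$cutUp) + sum(v <= cuts$cutLow)
    }, numeric(1)))
    if (!length(called) && false > 0 && !emptyNoted) {
      message("no genes called at delta = ", signif(delta, 3),
              "; FDR reported as 0")
      emptyNoted <<- TRUE
    }
    data.frame(delta = delta, called = length(called),
               medianFalse = false,
               fdr = if (length(called)) false / length(called) else 0)
  }))
  tab$fdr <- cummin(tab$fdr)
  rownames(tab) <- NULL

  res <- new("SamResult", d = d, s = setNames(obs$s, names(d)), s0 = s0,
             expectedD = expected, deltaTable = tab,
             called = character(), direction = character(),
             delta = numeric(), fdr = numeric(), excluded = excluded,
             foldAdmissible = names(d)[foldOk],
             config = list(nPermutations = ncol(permD),
                           s0Policy = s0Policy,
                           foldChange = foldChange, seed = seed))
  # calibrate at the requested target
  sel <- selectDeSam(res, fdrTarget, warnEmpty = FALSE)
  res@called <- sel$genes
  res@direction <- sel$direction
  res@delta <- sel$delta
  res@fdr <- sel$fdr
  validObject(res)
  res
}

#' Select DE genes from a SAM result at an FDR target
#'
#' Picks the smallest delta in the calibration grid whose estimated FDR
#' is at or below `fdrTarget` and returns the genes called there with
#' up-/down-regulation labels (UR for d > 0, DR for d < 0).
#'
#' @param result a [SamResult-class].
#' @param fdrTarget target false discovery rate (proportion).
#' @param warnEmpty warn when no delta achieves the target.
#' @return list with `genes` (character), `direction` (named "UR"/"DR"),
#'   `delta` and `fdr` (numeric scalars; `NA` when unachievable).
#' @export
selectDeSam <- function(result, fdrTarget = 0.0019, warnEmpty = TRUE) {
  stopifnot(is(result, "SamResult"), fdrTarget >= 0)
  tab <- result@deltaTable
  ok <- which(tab$fdr <= fdrTarget)
  if (!length(ok)) {
    if (warnEmpty)
      warning("no delta achieves FDR <= ", fdrTarget, "; returning empty set")
    return(list(genes = character(), direction = character(),
                delta = NA_real_, fdr = NA_real_))
  }
  delta <- tab$delta[min(ok)]
  dSorted <- sort(result@d)
  cuts <- .samCuts(dSorted, result@expectedD, delta)
  genes <- names(result@d)[result@d >= cuts$cutUp |
                             result@d <= cuts$cutLow]
  genes <- intersect(genes, result@foldAdmissible)
  direction <- setNames(as.character(ifelse(result@d[genes] > 0,
                                            "UR", "DR")), genes)
  list(genes = genes, direction = direction, delta = delta,
       fdr = tab$fdr[min(ok)])
}
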