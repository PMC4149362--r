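# Two-sample differential expression. The selection statistic is the
# two-sample t on per-gene control/disease summaries; the default is the
# Welch (unequal-variance) form with Welch-Satterthwaite degrees of
# freedom, with the classical pooled-variance form available. Selection
# uses raw two-sided P values with no multiplicity adjustment.

#' Per-gene group summaries
#'
#' Mean, sample standard deviation (n - 1 denominator) and sample count
#' per gene within each of the control and disease groups.
#'
#' @param dataset an [ExpressionDataset-class] with >= 2 samples per
#'   group.
#' @return data.frame with columns `gene`, `meanControl`, `sdControl`,
#'   `nControl`, `meanDisease`, `sdDisease`, `nDisease`.
#' @export
groupSummaries <- function(dataset) {
  m <- exprsValues(dataset)
  grp <- sampleGroups(dataset)
  nC <- sum(grp == "control"); nD <- sum(grp == "disease")
  if (nC < 2 || nD < 2)
    stop("need at least 2 samples per group (control: ", nC,
         ", disease: ", nD, ")")
  stat <- function(x) {
    mu <- rowMeans(x)
    list(mean = mu,
         sd = sqrt(rowSums((x - mu)^2) / (ncol(x) - 1)))
  }
  sc <- stat(m[, grp == "control", drop = FALSE])
  sd_ <- stat(m[, grp == "disease", drop = FALSE])
  data.frame(gene = rownames(m),
             meanControl = unname(sc$mean), sdControl = unname(sc$sd),
             nControl = nC,
             meanDisease = unname(sd_$mean), sdDisease = unname(sd_$sd),
             nDisease = nD,
             stringsAsFactors = FALSE)
}

#' Two-sample t statistics per gene
#'
#' Computes t = (mean control - mean disease) / SE per gene with a
#' two-sided P value from the t distribution. `variant = "welch"`
#' (default) uses SE = sqrt(s_c^2/n + s_d^2/m) with Welch-Satterthwaite
#' degrees of freedom; `"pooled"` uses the classical pooled-variance
#' form with n + m - 2 degrees of freedom. Genes whose two groups are
#' both constant at the same value have an undefined statistic and are
#' returned with `ok = FALSE` (excluded from selection) rather than a
#' silent zero.
#'
#' @param summaries output of [groupSummaries()] (or an
#'   [ExpressionDataset-class], summarised on the fly).
#' @param variant `"welch"` or `"pooled"`.
#' @return data.frame with columns `gene`, `t`, `df`, `p`, `ok`.
#' @export
tTest <- function(summaries, variant = c("welch", "pooled")) {
  variant <- match.arg(variant)
  if (is(summaries, "ExpressionDataset"))
    summaries <- groupSummaries(summaries)
  n <- summaries$nControl; m <- summaries$nDisease
  vC <- summaries$sdControl^2; vD <- summaries$sdDisease^2
  diff <- summaries$meanControl - summaries$meanDisease
  if (variant == "welch") {
    se2 <- vC / n + vD / m
    df <- se2^2 / (vC^2 / (n^2 * (n - 1)) + vD^2 / (m^2 * (m - 1)))
  } else {
    sp2 <- ((n - 1) * vC + (m - 1) * vD) / (n + m - 2)
    se2 <- sp2 * (1 / n + 1 / m)
    df <- n + m - 2
  }
  ok <- se2 > 0
  t <- ifelse(ok, diff / sqrt(se2), NA_real_)
  # both groups constant: distinct constants are infinitely separated
  t[!ok & diff != 0] <- Inf * sign(diff[!ok & diff != 0])
  defined <- ok | (diff != 0)
  p <- ifelse(is.finite(t), 2 * pt(-abs(t), df), ifelse(defined, 0, NA))
  data.frame(gene = summaries$gene, t = t, df = df, p = p,
             ok = defined, stringsAsFactors = FALSE)
}

#' Select DE genes by raw t-test P value
#'
#' Genes with two-sided P strictly below `alpha`; no multiple-testing
#' adjustment is applied. Genes with undefined statistics are excluded.
#'
#' @param records output of [tTest()].
#' @param alpha significance level in (0, 1\].
#' @return character vector of selected gene symbols.
#' @export
selectDeTtest <- function(records, alpha = 0.001) {
  stopifnot(alpha > 0, alpha <= 1)
  records$gene[records$ok & !is.na(records$p) & records$p < alpha]
}
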