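# Per-edge co-expression: Pearson correlation of the two endpoint genes
# across the control samples (C) and across the disease samples (D),
# the change C - D, and the percent of the maximum possible change
# (|C - D| <= 2 since r is confined to [-1, 1], so pct = 100 (C - D)/2).

#' Co-expression change and percent of maximum change
#'
#' @param rControl,rDisease Pearson correlations in \[-1, 1\].
#' @return data.frame with columns `change` (C - D) and `pctMaxChange`
#'   (100 (C - D) / 2).
#' @examples
#' coexpressionChange(0.236131, -0.15777)  # change 0.393901
#' @export
coexpressionChange <- function(rControl, rDisease) {
  stopifnot(all(abs(rControl) <= 1 + 1e-9), all(abs(rDisease) <= 1 + 1e-9))
  change <- rControl - rDisease
  data.frame(change = change, pctMaxChange = 100 * change / 2)
}

#' Per-edge co-expression records
#'
#' For each edge, the Pearson correlation of the two endpoint gene
#' vectors within the control samples and within the disease samples,
#' with the change and percent-of-maximum change. Edges with an
#' endpoint missing from the dataset are skipped with a message; edges
#' with a constant endpoint vector in either group have an undefined
#' correlation and are excluded with a warning (a silent zero would
#' corrupt the change statistics).
#'
#' @param edges data.frame with columns `node1`, `node2` (e.g.
#'   [networkEdges()] output), or a [QQPPINetwork-class].
#' @param dataset an [ExpressionDataset-class] with >= 3 samples per
#'   group.
#' @return data.frame with columns `node1`, `node2`, `rControl`,
#'   `rDisease`, `change`, `pctMaxChange`.
#' @export
edgeCoexpression <- function(edges, dataset) {
  if (is(edges, "QQPPINetwork")) edges <- networkEdges(edges)
  m <- exprsValues(dataset)
  grp <- sampleGroups(dataset)
  if (sum(grp == "control") < 3 || sum(grp == "disease") < 3)
    stop("Pearson correlation needs at least 3 samples per group")
  ctrl <- grp == "control"; dis <- grp == "disease"
  present <- edges$node1 %in% rownames(m) & edges$node2 %in% rownames(m)
  if (any(!present))
    message("skipped ", sum(!present),
            " edge(s) with endpoints missing from the dataset: ",
            paste(head(paste0(edges$node1[!present], "-",
                              edges$node2[!present]), 5),
                  collapse = ", "))
  edges <- edges[present, , drop = FALSE]
  if (!nrow(edges))
    return(data.frame(node1 = character(), node2 = character(),
                      rControl = numeric(), rDisease = numeric(),
                      change = numeric(), pctMaxChange = numeric(),
                      stringsAsFactors = FALSE))
  rC <- numeric(nrow(edges)); rD <- numeric(nrow(edges))
  defined <- logical(nrow(edges))
  for (i in seq_len(nrow(edges))) {
    x <- m[edges$node1[i], ]; y <- m[edges$node2[i], ]
    constant <- sd(x[ctrl]) == 0 || sd(y[ctrl]) == 0 ||
      sd(x[dis]) == 0 || sd(y[dis]) == 0
    if (constant) { defined[i] <- FALSE; next }
    rC[i] <- cor(x[ctrl], y[ctrl])
    rD[i] <- cor(x[dis], y[dis])
    defined[i] <- TRUE
  }
  if (any(!defined))
    warning("excluded ", sum(!defined),
            " edge(s) with a constant expression vector (undefined r)")
  edges <- edges[defined, , drop = FALSE]
  ch <- coexpressionChange(rC[defined], rD[defined])
  out <- data.frame(node1 = edges$node1, node2 = edges$node2,
                    rControl = rC[defined], rDisease = rD[defined],
                    change = ch$change, pctMaxChange = ch$pctMaxChange,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Co-expression of proteins interacting within matched complexes
#'
#' For each matched complex, co-expression records for every pair of
#' matched member proteins that is also a network edge, grouped under
#' the complex label in the output order.
#'
#' @param matches data.frame from [matchComplexes()].
#' @param netEdges data.frame of network edges (or a
#'   [QQPPINetwork-class]).
#' @param dataset an [ExpressionDataset-class].
#' @return data.frame with columns `complexId`, `complexName`, `node1`,
#'   `node2`, `rControl`, `rDisease`, `change`, `pctMaxChange`.
#' @export
complexCoexpression <- function(matches, netEdges, dataset) {
  if (is(netEdges, "QQPPINetwork")) netEdges <- networkEdges(netEdges)
  keys <- .edgeKey(netEdges)
  rows <- lapply(seq_len(nrow(matches)), function(i) {
    members <- strsplit(matches$matched[i], ";", fixed = TRUE)[[1]]
    if (length(members) < 2) return(NULL)
    pr <- combn(sort(members), 2)
    inNet <- paste0(pr[1, ], "\r", pr[2, ]) %in% keys
    if (!any(inNet)) return(NULL)
    rec <- edgeCoexpression(
      data.frame(node1 = pr[1, inNet], node2 = pr[2, inNet],
                 stringsAsFactors = FALSE), dataset)
    if (!nrow(rec)) return(NULL)
    cbind(data.frame(complexId = matches$id[i],
                     complexName = matches$name[i],
                     stringsAsFactors = FALSE), rec)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(complexId = character(), complexName = character(),
                      node1 = character(), node2 = character(),
                      rControl = numeric(), rDisease = numeric(),
                      change = numeric(), pctMaxChange = numeric(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
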