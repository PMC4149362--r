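# QQPPI network construction: induce the subgraph of an interactome on a
# query gene set (query-query edges only), merge networks from different
# interactome sources, and summarise global properties.

#' Build a Query-Query PPI network
#'
#' Keeps every interactome edge with both endpoints in the query set.
#' By default query genes with no such edge are excluded (only
#' interacting queries become nodes); `keepIsolated = TRUE` retains
#' them as isolated nodes.
#'
#' @param query character vector of query gene symbols (non-empty).
#' @param interactome an [Interactome-class].
#' @param keepIsolated keep edgeless query nodes?
#' @return a [QQPPINetwork-class]; edge provenance copies the
#'   interactome source tags.
#' @export
buildQQPPI <- function(query, interactome, keepIsolated = FALSE) {
  query <- unique(trimws(query))
  if (!length(query)) stop("query gene set must be non-empty")
  e <- networkEdges(interactome)
  keep <- e$node1 %in% query & e$node2 %in% query
  edges <- data.frame(node1 = e$node1[keep], node2 = e$node2[keep],
                      sources = e$source[keep], stringsAsFactors = FALSE)
  nodes <- if (keepIsolated) sort(query)
           else sort(unique(c(edges$node1, edges$node2)))
  .newQQPPI(nodes, edges)
}

#' Merge two QQPPI networks
#'
#' Union semantics: the merged network contains every node and every
#' interaction present in either input (an edge supported by both
#' appears once, with the provenance tags of both). `mode =
#' "intersection"` instead keeps only edges present in both inputs.
#'
#' @param a,b [QQPPINetwork-class] objects.
#' @param mode `"union"` (default) or `"intersection"`.
#' @return a [QQPPINetwork-class].
#' @export
mergeNetworks <- function(a, b, mode = c("union", "intersection")) {
  mode <- match.arg(mode)
  ea <- networkEdges(a); eb <- networkEdges(b)
  keyA <- .edgeKey(ea); keyB <- .edgeKey(eb)
  joinSources <- function(...)
    paste(sort(unique(unlist(strsplit(c(...), ";", fixed = TRUE)))),
          collapse = ";")
  if (mode == "union") {
    keys <- union(keyA, keyB)
    edges <- do.call(rbind, lapply(keys, function(k) {
      ia <- match(k, keyA); ib <- match(k, keyB)
      src <- joinSources(if (!is.na(ia)) ea$sources[ia],
                         if (!is.na(ib)) eb$sources[ib])
      ref <- if (!is.na(ia)) ea[ia, ] else eb[ib, ]
      data.frame(node1 = ref$node1, node2 = ref$node2, sources = src,
                 stringsAsFactors = FALSE)
    }))
    nodes <- sort(union(networkNodes(a), networkNodes(b)))
  } else {
    keys <- intersect(keyA, keyB)
    edges <- do.call(rbind, lapply(keys, function(k) {
      ia <- match(k, keyA); ib <- match(k, keyB)
      data.frame(node1 = ea$node1[ia], node2 = ea$node2[ia],
                 sources = joinSources(ea$sources[ia], eb$sources[ib]),
                 stringsAsFactors = FALSE)
    }))
    nodes <- sort(unique(c(edges$node1, edges$node2)))
  }
  if (is.null(edges))
    edges <- data.frame(node1 = character(), node2 = character(),
                        sources = character(), stringsAsFactors = FALSE)
  edges <- edges[order(edges$node1, edges$node2), , drop = FALSE]
  .newQQPPI(nodes, edges)
}

#' Global network statistics
#'
#' Node/edge counts, average and maximum degree, average and maximum
#' betweenness. Averages are reported both exactly and rounded to the
#' table precision (1 decimal for degree, 2 for betweenness).
#'
#' @param net a [QQPPINetwork-class].
#' @param topo a [TopologyAttributes-class] computed on `net` (computed
#'   on the fly when omitted).
#' @return data.frame with one row: `nNodes`, `nEdges`, `avgDegree`,
#'   `avgDegreeRounded`, `maxDegree`, `avgBetweenness`,
#'   `avgBetweennessRounded`, `maxBetweenness`.
#' @export
networkSummary <- function(net, topo = computeTopology(net)) {
  nNodes <- length(networkNodes(net))
  nEdges <- nrow(networkEdges(net))
  if (nNodes == 0) {
    warning("empty network: all statistics are zero")
    return(data.frame(nNodes = 0, nEdges = 0, avgDegree = 0,
                      avgDegreeRounded = 0, maxDegree = 0,
                      avgBetweenness = 0, avgBetweennessRounded = 0,
                      maxBetweenness = 0))
  }
  deg <- degreeOf(topo); btw <- betweennessOf(topo)
  data.frame(nNodes = nNodes, nEdges = nEdges,
             avgDegree = 2 * nEdges / nNodes,
             avgDegreeRounded = round(2 * nEdges / nNodes, 1),
             maxDegree = max(deg),
             avgBetweenness = mean(btw),
             avgBetweennessRounded = round(mean(btw), 2),
             maxBetweenness = max(btw))
}
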