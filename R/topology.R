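# Topology: degree and Brandes betweenness centrality, the hub degree
# cutoff M + 2S, and the hub/bottleneck classification rules.
# Betweenness convention: unweighted shortest paths, each unordered
# (s, t) pair counted once, endpoints excluded, unnormalised; on
# disconnected networks paths are counted within components.

#' Compute degree and betweenness for every node
#'
#' @param net a [QQPPINetwork-class].
#' @return a [TopologyAttributes-class].
#' @examples
#' net <- buildQQPPI(c("A", "B", "C"),
#'                   Interactome(c("A", "B"), c("B", "C")))
#' betweennessOf(computeTopology(net))  # B separates one pair
#' @export
computeTopology <- function(net) {
  g <- asIgraph(net)
  nodes <- networkNodes(net)
  deg <- igraph::degree(g)
  btw <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  new("TopologyAttributes",
      degree = setNames(as.numeric(deg[nodes]), nodes),
      betweenness = setNames(as.numeric(btw[nodes]), nodes))
}

#' Hub degree cutoff: mean plus twice the standard deviation
#'
#' @param topo a [TopologyAttributes-class] (>= 2 nodes).
#' @param sdMode `"sample"` (n - 1 denominator, default) or
#'   `"population"`.
#' @return a [HubCutoff-class]. A zero standard deviation (regular
#'   graph) makes the cutoff degenerate - every node reaches it - and is
#'   flagged with a warning.
#' @export
hubCutoff <- function(topo, sdMode = c("sample", "population")) {
  sdMode <- match.arg(sdMode)
  deg <- degreeOf(topo)
  if (length(deg) < 2)
    stop("hub cutoff needs at least 2 nodes, got ", length(deg))
  M <- mean(deg)
  S <- if (sdMode == "sample") sd(deg)
       else sqrt(mean((deg - M)^2))
  if (S == 0)
    warning("degree distribution is constant (S = 0): ",
            "the hub cutoff is degenerate and every node reaches it")
  new("HubCutoff", meanDegree = M, sdDegree = S, cutoff = M + 2 * S,
      roundedCutoff = round(M + 2 * S), sdMode = sdMode)
}

# arithmetic-only constructor used when the moments are given (e.g.
# recomputing a printed summary table)
#' @rdname hubCutoff
#' @param meanDegree,sdDegree degree-distribution moments, when building
#'   the cutoff from known moments rather than a network.
#' @export
hubCutoffFromMoments <- function(meanDegree, sdDegree,
                                 sdMode = "sample") {
  new("HubCutoff", meanDegree = meanDegree, sdDegree = sdDegree,
      cutoff = meanDegree + 2 * sdDegree,
      roundedCutoff = round(meanDegree + 2 * sdDegree), sdMode = sdMode)
}

#' Classify hubs
#'
#' Hubs (high-connectivity nodes) are nodes whose degree is greater
#' than or equal to the unrounded cutoff M + 2S. Degrees are integers,
#' so e.g. degree >= 11.8 is equivalent to degree >= 12.
#'
#' @param topo a [TopologyAttributes-class].
#' @param cutoff a [HubCutoff-class] computed on the same network.
#' @return character vector of hub gene symbols.
#' @export
classifyHubs <- function(topo, cutoff) {
  deg <- degreeOf(topo)
  names(deg)[deg >= cutoff@cutoff]
}

#' Classify bottlenecks
#'
#' Bottlenecks (high-betweenness, low-connectivity nodes) satisfy all
#' three of: (i) betweenness in the top half of the descending-sorted
#' distribution, with ties at the boundary value included; (ii) degree
#' strictly below the hub cutoff; (iii) at least two hub neighbours.
#'
#' @param net the [QQPPINetwork-class].
#' @param topo its [TopologyAttributes-class].
#' @param hubSet character vector from [classifyHubs()].
#' @param cutoff the [HubCutoff-class] used for the hubs.
#' @return character vector of bottleneck gene symbols.
#' @export
classifyBottlenecks <- function(net, topo, hubSet, cutoff) {
  nodes <- networkNodes(net)
  if (length(nodes) == 0 || length(hubSet) < 2) return(character())
  btw <- betweennessOf(topo)
  deg <- degreeOf(topo)
  boundary <- sort(btw, decreasing = TRUE)[ceiling(length(btw) / 2)]
  topHalf <- btw >= boundary
  e <- networkEdges(net)
  hubNbr <- setNames(numeric(length(nodes)), nodes)
  isHub1 <- e$node1 %in% hubSet
  isHub2 <- e$node2 %in% hubSet
  t1 <- table(e$node1[isHub2]); t2 <- table(e$node2[isHub1])
  hubNbr[names(t1)] <- hubNbr[names(t1)] + as.numeric(t1)
  hubNbr[names(t2)] <- hubNbr[names(t2)] + as.numeric(t2)
  names(btw)[topHalf & deg < cutoff@cutoff & hubNbr >= 2]
}

#' Classify every node of a network
#'
#' Runs [computeTopology()], [hubCutoff()], [classifyHubs()] and
#' [classifyBottlenecks()] and assembles the evidence table.
#'
#' @param net a [QQPPINetwork-class].
#' @param sdMode passed to [hubCutoff()].
#' @param topo optionally, precomputed [TopologyAttributes-class].
#' @return a [NodeClassification-class].
#' @export
classifyNodes <- function(net, sdMode = "sample",
                          topo = computeTopology(net)) {
  cutoff <- hubCutoff(topo, sdMode)
  hubSet <- classifyHubs(topo, cutoff)
  bnSet <- classifyBottlenecks(net, topo, hubSet, cutoff)
  nodes <- networkNodes(net)
  e <- networkEdges(net)
  hubNbr <- vapply(nodes, function(v) {
    nbr <- c(e$node2[e$node1 == v], e$node1[e$node2 == v])
    sum(nbr %in% hubSet)
  }, numeric(1))
  role <- rep("other", length(nodes))
  role[nodes %in% hubSet] <- "hub"
  role[nodes %in% bnSet] <- "bottleneck"
  ev <- data.frame(node = nodes,
                   degree = unname(degreeOf(topo)[nodes]),
                   betweenness = unname(betweennessOf(topo)[nodes]),
                   hubNeighbors = unname(hubNbr),
                   role = role, stringsAsFactors = FALSE)
  new("NodeClassification", hubs = sort(hubSet), bottlenecks = sort(bnSet),
      evidence = ev, cutoff = cutoff)
}
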