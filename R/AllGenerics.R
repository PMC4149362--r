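#' Network and catalog accessors
#'
#' Accessor generics for the package's S4 containers: node and edge sets
#' of networks and interactomes, hub/bottleneck sets of a classification,
#' and the degree/betweenness vectors of topology attributes.
#'
#' @param x the object.
#' @return `networkNodes`/`hubs`/`bottlenecks` return character vectors;
#'   `networkEdges` returns a data.frame; `degreeOf`/`betweennessOf`
#'   return named numeric vectors.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))

#' @rdname accessors
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' @rdname accessors
#' @export
setGeneric("hubs", function(x) standardGeneric("hubs"))

#' @rdname accessors
#' @export
setGeneric("bottlenecks", function(x) standardGeneric("bottlenecks"))

#' @rdname accessors
#' @export
setGeneric("degreeOf", function(x) standardGeneric("degreeOf"))

#' @rdname accessors
#' @export
setGeneric("betweennessOf", function(x) standardGeneric("betweennessOf"))

#' Convert a package network object to an igraph graph
#'
#' @param x an [Interactome-class] or [QQPPINetwork-class].
#' @return an undirected simple `igraph` graph with named vertices.
#' @export
setGeneric("asIgraph", function(x) standardGeneric("asIgraph"))

#' @rdname accessors
#' @export
setMethod("networkNodes", "QQPPINetwork", function(x) x@nodes)

#' @rdname accessors
#' @export
setMethod("networkEdges", "QQPPINetwork", function(x) x@edges)

#' @rdname accessors
#' @export
setMethod("networkNodes", "Interactome",
          function(x) sort(unique(c(x@edges$node1, x@edges$node2))))

#' @rdname accessors
#' @export
setMethod("networkEdges", "Interactome", function(x) x@edges)

#' @rdname accessors
#' @export
setMethod("hubs", "NodeClassification", function(x) x@hubs)

#' @rdname accessors
#' @export
setMethod("bottlenecks", "NodeClassification", function(x) x@bottlenecks)

#' @rdname accessors
#' @export
setMethod("degreeOf", "TopologyAttributes", function(x) x@degree)

#' @rdname accessors
#' @export
setMethod("betweennessOf", "TopologyAttributes", function(x) x@betweenness)

setMethod("asIgraph", "QQPPINetwork", function(x) {
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(x@nodes), name = x@nodes)
  if (nrow(x@edges))
    g <- igraph::add_edges(g, rbind(x@edges$node1, x@edges$node2))
  g
})

setMethod("asIgraph", "Interactome", function(x) {
  nodes <- networkNodes(x)
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(nodes), name = nodes)
  if (nrow(x@edges))
    g <- igraph::add_edges(g, rbind(x@edges$node1, x@edges$node2))
  g
})

setMethod("show", "QQPPINetwork", function(object) {
  cat("QQPPINetwork with", length(object@nodes), "nodes and",
      nrow(object@edges), "edges\n")
  if (length(object@nodes))
    cat("  nodes:", paste(head(object@nodes, 5), collapse = ", "),
        if (length(object@nodes) > 5) "..." else "", "\n")
})

setMethod("show", "Interactome", function(object) {
  cat("Interactome with", length(networkNodes(object)), "proteins and",
      nrow(object@edges), "interactions\n")
  src <- unique(object@edges$source)
  if (length(src))
    cat("  sources:", paste(head(src, 5), collapse = ", "), "\n")
})

setMethod("show", "NodeClassification", function(object) {
  cat("NodeClassification:", length(object@hubs), "hubs,",
      length(object@bottlenecks), "bottlenecks",
      sprintf("(cutoff %.1f + 2*%.1f = %.1f)\n",
              object@cutoff@meanDegree, object@cutoff@sdDegree,
              object@cutoff@cutoff))
})

setMethod("show", "HubCutoff", function(object) {
  cat(sprintf("HubCutoff: M = %.4g, S = %.4g (%s), M + 2S = %.4g ~ %d\n",
              object@meanDegree, object@sdDegree, object@sdMode,
              object@cutoff, as.integer(object@roundedCutoff)))
})

setMethod("show", "SamResult", function(object) {
  cat("SamResult:", length(object@d), "genes, s0 =",
      signif(object@s0, 4), "\n")
  if (length(object@delta))
    cat(sprintf("  delta = %.4g, estimated FDR = %.4g, %d called (%d UR, %d DR)\n",
                object@delta, object@fdr, length(object@called),
                sum(object@direction == "UR"),
                sum(object@direction == "DR")))
})

setMethod("show", "CoreModule", function(object) {
  cat("CoreModule:", length(object@nodes), "nodes,",
      nrow(object@edges), "edges\n")
})

setMethod("show", "ComplexCatalog", function(object) {
  cat("ComplexCatalog with", nrow(object@info), "complexes\n")
})

setMethod("show", "TermAnnotation", function(object) {
  cat("TermAnnotation with", nrow(object@info), "terms in namespace(s):",
      paste(unique(object@info$namespace), collapse = ", "), "\n")
})

setMethod("show", "SyntheticSpec", function(object) {
  cat("SyntheticSpec:", object@nGenes, "genes,",
      object@nControl, "control +", object@nDisease, "disease samples;",
      object@interactomeModel, "interactome on", object@nProteins,
      "proteins; seed", object@seed, "\n")
})
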