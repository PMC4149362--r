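# 3- and 4-clique enumeration and the core functional module. The
# enumerator is an edge-iterator: triangles come from common-neighbour
# intersection over each edge (with both endpoints below the common
# neighbour in node order, so each triangle is produced once), and
# 4-cliques extend each triangle by a common neighbour above its largest
# member. A common neighbour of any 4-clique would witness a 5-clique;
# its presence is detected and warned about.

# adjacency as a named list of sorted neighbour character vectors
.adjacency <- function(net) {
  e <- networkEdges(net)
  nodes <- networkNodes(net)
  adj <- setNames(vector("list", length(nodes)), nodes)
  for (v in nodes) adj[[v]] <- character()
  if (nrow(e)) {
    sp1 <- split(e$node2, e$node1)
    sp2 <- split(e$node1, e$node2)
    for (v in names(sp1)) adj[[v]] <- c(adj[[v]], sp1[[v]])
    for (v in names(sp2)) adj[[v]] <- c(adj[[v]], sp2[[v]])
    adj <- lapply(adj, sort)
  }
  adj
}

#' Enumerate 3- or 4-cliques
#'
#' Returns every complete subgraph of size `k` exactly once, in
#' canonical (lexicographically sorted) form. By default all complete
#' subgraphs are counted, so every 4-clique also contributes its four
#' triangles to the 3-clique list; `maximalOnly = TRUE` excludes
#' k-cliques contained in a (k+1)-clique. A warning is issued when the
#' network contains a 5-clique.
#'
#' @param net a [QQPPINetwork-class].
#' @param k clique size, 3 or 4.
#' @param maximalOnly exclude cliques contained in a (k+1)-clique?
#' @return list of sorted character vectors of length `k`.
#' @export
enumerateKCliques <- function(net, k, maximalOnly = FALSE) {
  stopifnot(k %in% c(3, 4))
  adj <- .adjacency(net)
  e <- networkEdges(net)
  triangles <- list()
  if (nrow(e)) {
    for (i in seq_len(nrow(e))) {
      a <- e$node1[i]; b <- e$node2[i]     # a < b (canonical)
      common <- intersect(adj[[a]], adj[[b]])
      for (w in common[common > b])
        triangles[[length(triangles) + 1L]] <- c(a, b, w)
    }
  }
  quads <- list()
  for (tri in triangles) {
    common <- Reduce(intersect, adj[tri])
    for (w in common[common > tri[3]])
      quads[[length(quads) + 1L]] <- c(tri, w)
  }
  # 5-clique witness: a common neighbour of all four members
  for (q in quads) {
    if (length(Reduce(intersect, adj[q]))) {
      warning("the network contains at least one 5-clique; ",
              "only 3- and 4-cliques are enumerated")
      break
    }
  }
  if (k == 3) {
    if (maximalOnly && length(quads)) {
      inQuad <- unique(unlist(lapply(quads, function(q)
        combn(q, 3, paste, collapse = "\r"))))
      triangles <- triangles[!vapply(triangles, paste, "",
                                     collapse = "\r") %in% inQuad]
    }
    return(triangles)
  }
  if (maximalOnly && length(quads)) {
    keep <- vapply(quads, function(q)
      length(Reduce(intersect, adj[q])) == 0, logical(1))
    quads <- quads[keep]
  }
  quads
}

#' Assemble the core functional module
#'
#' The union of all supplied 3- and 4-cliques: its nodes are every
#' clique member, its edges every within-clique pair, and each node
#' carries its occurrence counts in 3- and 4-cliques.
#'
#' @param cliques3,cliques4 lists from [enumerateKCliques()].
#' @param net the host [QQPPINetwork-class] (edge sanity check).
#' @return a [CoreModule-class].
#' @export
coreFunctionalModule <- function(cliques3, cliques4, net) {
  all <- c(cliques3, cliques4)
  if (!length(all))
    return(new("CoreModule", nodes = character(),
               edges = data.frame(node1 = character(),
                                  node2 = character(),
                                  stringsAsFactors = FALSE),
               occurrence3 = setNames(numeric(), character()),
               occurrence4 = setNames(numeric(), character())))
  nodes <- sort(unique(unlist(all)))
  pairs <- unique(unlist(lapply(all, function(cl)
    combn(sort(cl), 2, paste, collapse = "\r"))))
  parts <- strsplit(pairs, "\r", fixed = TRUE)
  edges <- data.frame(node1 = vapply(parts, `[`, "", 1),
                      node2 = vapply(parts, `[`, "", 2),
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$node1, edges$node2), , drop = FALSE]
  rownames(edges) <- NULL
  hostKeys <- .edgeKey(networkEdges(net))
  if (!all(paste0(edges$node1, "\r", edges$node2) %in% hostKeys))
    stop("clique edges are not all present in the host network; ",
         "were the cliques computed on this network?")
  countIn <- function(cliques) {
    cnt <- setNames(numeric(length(nodes)), nodes)
    if (length(cliques)) {
      t <- table(unlist(cliques))
      cnt[names(t)] <- as.numeric(t)
    }
    cnt
  }
  new("CoreModule", nodes = nodes, edges = edges,
      occurrence3 = countIn(cliques3), occurrence4 = countIn(cliques4))
}
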