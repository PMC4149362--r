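# User-facing constructors for the core containers. Internal helpers keep
# edge tables in canonical form (node1 < node2, deduplicated, no loops).

# canonicalise an edge table; returns data.frame(node1, node2) plus any
# extra columns aggregated by `collapseExtra` (a function applied per edge)
.canonicalEdges <- function(node1, node2, source = NULL) {
  if (!length(node1)) {
    out <- data.frame(node1 = character(), node2 = character(),
                      stringsAsFactors = FALSE)
    if (!is.null(source)) out$source <- character()
    attr(out, "droppedSelfLoops") <- 0L
    return(out)
  }
  node1 <- trimws(as.character(node1))
  node2 <- trimws(as.character(node2))
  keep <- node1 != node2
  nLoops <- sum(!keep)
  node1 <- node1[keep]; node2 <- node2[keep]
  if (!is.null(source)) source <- as.character(source)[keep]
  if (!length(node1)) {
    out <- data.frame(node1 = character(), node2 = character(),
                      stringsAsFactors = FALSE)
    if (!is.null(source)) out$source <- character()
    attr(out, "droppedSelfLoops") <- nLoops
    return(out)
  }
  swap <- node1 > node2
  tmp <- node1[swap]; node1[swap] <- node2[swap]; node2[swap] <- tmp
  key <- paste0(node1, "\r", node2)
  if (is.null(source)) {
    dup <- duplicated(key)
    out <- data.frame(node1 = node1[!dup], node2 = node2[!dup],
                      stringsAsFactors = FALSE)
  } else {
    first <- !duplicated(key)
    src <- vapply(split(source, factor(key, levels = key[first])),
                  function(s) paste(sort(unique(s)), collapse = ";"), "")
    out <- data.frame(node1 = node1[first], node2 = node2[first],
                      source = unname(src), stringsAsFactors = FALSE)
  }
  attr(out, "droppedSelfLoops") <- nLoops
  out
}

.edgeKey <- function(edges) {
  if (!nrow(edges)) return(character())
  paste0(edges$node1, "\r", edges$node2)
}

#' Construct an ExpressionDataset
#'
#' @param values numeric matrix of log2 expression, genes in rows (unique
#'   rownames), samples in columns (unique colnames).
#' @param group character/factor of length `ncol(values)` with values
#'   `"control"`/`"disease"`, or a named vector mapping sample to group.
#' @return an [ExpressionDataset-class].
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("G", 1:3), paste0("S", 1:4)))
#' ExpressionDataset(m, c("control", "control", "disease", "disease"))
#' @export
ExpressionDataset <- function(values, group) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix must have gene rownames and sample colnames")
  if (!is.null(names(group))) {
    missing <- setdiff(colnames(values), names(group))
    if (length(missing))
      stop("no group assignment for sample(s): ",
           paste(missing, collapse = ", "))
    group <- group[colnames(values)]
  }
  if (length(group) != ncol(values))
    stop("group must have one entry per sample")
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = values),
    colData = S4Vectors::DataFrame(group = as.character(group),
                                   row.names = colnames(values)))
  new("ExpressionDataset", se)
}

#' Expression values and sample groups
#'
#' @param x an [ExpressionDataset-class].
#' @return `exprsValues` the log2 matrix; `sampleGroups` a named character
#'   vector of `"control"`/`"disease"` labels.
#' @export
exprsValues <- function(x) SummarizedExperiment::assay(x, "exprs")

#' @rdname exprsValues
#' @export
sampleGroups <- function(x) {
  setNames(as.character(SummarizedExperiment::colData(x)$group),
           colnames(x))
}

#' Construct an Interactome from an edge list
#'
#' Self-interactions are dropped (with a message when present) and
#' duplicate unordered pairs are merged; source tags of merged duplicates
#' are combined.
#'
#' @param node1,node2 character vectors of interacting gene symbols.
#' @param source a single source tag or one per edge.
#' @return an [Interactome-class].
#' @export
Interactome <- function(node1 = character(), node2 = character(),
                        source = "interactome") {
  if (length(node1) != length(node2))
    stop("node1 and node2 must have the same length")
  if (length(source) == 1) source <- rep(source, length(node1))
  edges <- .canonicalEdges(node1, node2, source)
  nLoops <- attr(edges, "droppedSelfLoops")
  if (nLoops > 0)
    message("dropped ", nLoops, " self-interaction(s)")
  attr(edges, "droppedSelfLoops") <- NULL
  new("Interactome", edges = edges)
}

# internal: build a QQPPINetwork from canonical pieces
.newQQPPI <- function(nodes, edges) {
  rownames(edges) <- NULL
  new("QQPPINetwork", nodes = nodes, edges = edges)
}

#' Construct a ComplexCatalog
#'
#' @param id,name character vectors (ids unique).
#' @param members list of character gene vectors, one per complex.
#' @return a [ComplexCatalog-class].
#' @export
ComplexCatalog <- function(id = character(), name = character(),
                           members = list()) {
  id <- as.character(id)
  if (anyDuplicated(id)) stop("duplicate complex id(s): ",
                              paste(unique(id[duplicated(id)]), collapse = ", "))
  members <- lapply(members, function(m) unique(trimws(as.character(m))))
  names(members) <- id
  new("ComplexCatalog",
      info = data.frame(id = id, name = as.character(name),
                        stringsAsFactors = FALSE),
      members = members)
}

#' Construct a TermAnnotation
#'
#' @param id,name,namespace character vectors (ids unique).
#' @param genes list of character gene vectors, one per term.
#' @return a [TermAnnotation-class].
#' @export
TermAnnotation <- function(id = character(), name = character(),
                           namespace = "BP", genes = list()) {
  id <- as.character(id)
  if (anyDuplicated(id)) stop("duplicate term id(s): ",
                              paste(unique(id[duplicated(id)]), collapse = ", "))
  if (length(namespace) == 1) namespace <- rep(namespace, length(id))
  genes <- lapply(genes, function(g) unique(trimws(as.character(g))))
  names(genes) <- id
  new("TermAnnotation",
      info = data.frame(id = id, name = as.character(name),
                        namespace = as.character(namespace),
                        stringsAsFactors = FALSE),
      genes = genes)
}

#' Term gene sets and complex member sets
#'
#' @param x a [TermAnnotation-class] or [ComplexCatalog-class].
#' @return a named list of character gene vectors.
#' @export
geneSets <- function(x) {
  if (is(x, "TermAnnotation")) return(x@genes)
  if (is(x, "ComplexCatalog")) return(x@members)
  stop("no gene sets for objects of class ", class(x))
}

#' @rdname geneSets
#' @export
termInfo <- function(x) {
  if (is(x, "TermAnnotation")) return(x@info)
  if (is(x, "ComplexCatalog")) return(x@info)
  stop("no info table for objects of class ", class(x))
}
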