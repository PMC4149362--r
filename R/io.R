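# Readers and writers for every on-disk format the pipeline touches:
# expression/phenotype TSV, SIF edge lists, GMT annotations, complex
# catalogs, gene lists, GraphML. Readers tolerate CRLF line endings and
# trailing whitespace; report floats are printed with 6 decimals.

.readTextLines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sub("[ \t\r]+$", "", readLines(path, warn = FALSE))
}

.writeMatrixTsv <- function(m, path, idColumn = "gene") {
  lines <- c(paste(c(idColumn, colnames(m)), collapse = "\t"),
             vapply(seq_len(nrow(m)), function(i)
               paste(c(rownames(m)[i], sprintf("%.6f", m[i, ])),
                     collapse = "\t"), ""))
  writeLines(lines, path)
}

#' Read an expression matrix and phenotype table
#'
#' The matrix file is TSV with a header row of sample identifiers and
#' gene symbols in the first column; the phenotype file is TSV with
#' columns `sample` and `group` (`control`/`disease`). Rows sharing a
#' gene symbol (multiple probes) are collapsed according to `collapse`:
#' elementwise mean (default), the row with the highest mean
#' (`"maxmean"`), or the first row encountered (`"first"`).
#'
#' @param matrixPath,phenotypePath file paths.
#' @param collapse probe-collapse policy.
#' @return an [ExpressionDataset-class].
#' @export
readExpression <- function(matrixPath, phenotypePath,
                           collapse = c("mean", "maxmean", "first")) {
  collapse <- match.arg(collapse)
  lines <- .readTextLines(matrixPath)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty expression file: ", matrixPath)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  samples <- trimws(header[-1])
  body <- strsplit(lines[-1], "\t", fixed = TRUE)
  nc <- length(header)
  genes <- character(length(body))
  m <- matrix(NA_real_, length(body), length(samples))
  for (i in seq_along(body)) {
    f <- body[[i]]
    if (length(f) != nc)
      stop("malformed expression row at line ", i + 1, ": expected ",
           nc, " fields, found ", length(f))
    genes[i] <- trimws(f[1])
    v <- suppressWarnings(as.numeric(f[-1]))
    if (anyNA(v)) {
      j <- which(is.na(v))[1]
      stop("non-numeric expression value '", f[-1][j], "' at row ", i,
           " (gene ", genes[i], "), column ", samples[j])
    }
    m[i, ] <- v
  }
  if (anyDuplicated(genes)) {
    idx <- split(seq_along(genes), genes)
    collapsed <- t(vapply(idx, function(rows) {
      if (length(rows) == 1) return(m[rows, ])
      switch(collapse,
             mean = colMeans(m[rows, , drop = FALSE]),
             maxmean = m[rows[which.max(rowMeans(m[rows, , drop = FALSE]))], ],
             first = m[rows[1], ])
    }, numeric(length(samples))))
    # keep first-appearance gene order
    ord <- match(unique(genes), names(idx))
    m <- collapsed[ord, , drop = FALSE]
    genes <- unique(genes)
  }
  dimnames(m) <- list(genes, samples)
  ph <- .readTextLines(phenotypePath)
  ph <- ph[nzchar(ph)]
  pf <- do.call(rbind, strsplit(ph, "\t", fixed = TRUE))
  if (ncol(pf) < 2) stop("phenotype file must have sample and group columns")
  if (identical(tolower(trimws(pf[1, 1])), "sample")) pf <- pf[-1, , drop = FALSE]
  groupMap <- setNames(trimws(pf[, 2]), trimws(pf[, 1]))
  missing <- setdiff(samples, names(groupMap))
  if (length(missing))
    stop("sample(s) missing from phenotype file: ",
         paste(missing, collapse = ", "))
  ExpressionDataset(m, groupMap[samples])
}

#' Write an expression matrix and phenotype table
#'
#' Values are printed with 6 decimal places; a write/read/write cycle is
#' byte-stable.
#'
#' @param dataset an [ExpressionDataset-class].
#' @param matrixPath,phenotypePath output paths.
#' @return invisibly, `matrixPath`.
#' @export
writeExpression <- function(dataset, matrixPath, phenotypePath = NULL) {
  .writeMatrixTsv(exprsValues(dataset), matrixPath)
  if (!is.null(phenotypePath))
    writePhenotype(sampleGroups(dataset), phenotypePath)
  invisible(matrixPath)
}

#' @rdname writeExpression
#' @param groups named character vector sample -> group.
#' @param path output path.
#' @export
writePhenotype <- function(groups, path) {
  writeLines(c("sample\tgroup", paste(names(groups), groups, sep = "\t")),
             path)
  invisible(path)
}

#' Read a SIF interaction file
#'
#' Accepts `A <relation> B` (three fields) or `A<TAB>B` (two fields)
#' lines. Edges are undirected and deduplicated; self-interactions are
#' dropped with a message reporting the count.
#'
#' @param path file path.
#' @param source source tag attached to every edge (defaults to the file
#'   name).
#' @return an [Interactome-class].
#' @export
readSif <- function(path, source = basename(path)) {
  lines <- .readTextLines(path)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  if (!length(lines))
    return(Interactome(character(), character(), source))
  fields <- strsplit(lines, "[\t ]+")
  n1 <- character(length(fields)); n2 <- character(length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]][nzchar(fields[[i]])]
    if (length(f) == 2) { n1[i] <- f[1]; n2[i] <- f[2] }
    else if (length(f) == 3) { n1[i] <- f[1]; n2[i] <- f[3] }
    else stop("malformed SIF line ", which(keep)[i], " in ", path,
              ": expected 2 or 3 fields, found ", length(f))
  }
  Interactome(n1, n2, source)
}

#' Write an interactome or network as SIF
#'
#' @param x an [Interactome-class] or [QQPPINetwork-class].
#' @param path output path.
#' @param relation relation label for the middle column.
#' @return invisibly, `path`.
#' @export
writeSif <- function(x, path, relation = "pp") {
  e <- networkEdges(x)
  writeLines(if (nrow(e)) paste(e$node1, relation, e$node2, sep = "\t")
             else character(), path)
  invisible(path)
}

#' Read a GMT term-annotation file
#'
#' Standard GMT: term id, description, then one gene per field. A
#' description of the form `"namespace|name"` is split into the two
#' parts; otherwise the whole description is the term name and
#' `namespace` defaults to `"BP"`.
#'
#' @param path file path.
#' @param namespace fallback namespace label.
#' @return a [TermAnnotation-class].
#' @export
readGmt <- function(path, namespace = "BP") {
  lines <- .readTextLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    return(TermAnnotation(character(), character(), genes = list()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3)
  if (length(bad))
    stop("malformed GMT line ", bad[1], ": need id, description and ",
         "at least one gene")
  ids <- vapply(fields, `[`, "", 1)
  if (anyDuplicated(ids))
    stop("duplicate term id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  desc <- vapply(fields, `[`, "", 2)
  hasNs <- grepl("|", desc, fixed = TRUE)
  ns <- ifelse(hasNs, sub("\\|.*$", "", desc), namespace)
  nm <- ifelse(hasNs, sub("^[^|]*\\|", "", desc), desc)
  TermAnnotation(ids, nm, ns,
                 genes = lapply(fields, function(f) f[-(1:2)]))
}

#' @rdname readGmt
#' @param annotation a [TermAnnotation-class] to write.
#' @export
writeGmt <- function(annotation, path) {
  info <- termInfo(annotation)
  sets <- geneSets(annotation)
  writeLines(vapply(seq_len(nrow(info)), function(i)
    paste(c(info$id[i], paste0(info$namespace[i], "|", info$name[i]),
            sets[[i]]), collapse = "\t"), character(1)), path)
  invisible(path)
}

#' Read/write a complex catalog
#'
#' Catalog TSV rows are `id<TAB>name<TAB>member1;member2;...`; a header
#' line starting with `id` is tolerated. Duplicate ids are an error.
#'
#' @param path file path.
#' @return a [ComplexCatalog-class].
#' @export
readComplexCatalog <- function(path) {
  lines <- .readTextLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) &&
      identical(tolower(strsplit(lines[1], "\t")[[1]][1]), "id"))
    lines <- lines[-1]
  if (!length(lines))
    return(ComplexCatalog(character(), character(), list()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3)
  if (length(bad))
    stop("malformed catalog line ", bad[1],
         ": expected id, name and members")
  ids <- vapply(fields, `[`, "", 1)
  if (anyDuplicated(ids))
    stop("duplicate complex id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  ComplexCatalog(ids, vapply(fields, `[`, "", 2),
                 lapply(fields, function(f)
                   trimws(strsplit(f[3], ";", fixed = TRUE)[[1]])))
}

#' @rdname readComplexCatalog
#' @param catalog a [ComplexCatalog-class] to write.
#' @export
writeComplexCatalog <- function(catalog, path) {
  info <- termInfo(catalog)
  members <- geneSets(catalog)
  writeLines(c("id\tname\tmembers",
               vapply(seq_len(nrow(info)), function(i)
                 paste(info$id[i], info$name[i],
                       paste(members[[i]], collapse = ";"), sep = "\t"),
                 character(1))), path)
  invisible(path)
}

#' Read a flat gene list (one symbol per line)
#'
#' Blank lines and leading/trailing whitespace are ignored; duplicates
#' are removed.
#'
#' @param path file path.
#' @return a character vector of gene symbols.
#' @export
readGeneList <- function(path) {
  lines <- trimws(.readTextLines(path))
  unique(lines[nzchar(lines)])
}

#' Write a QQPPI network as GraphML
#'
#' Node attributes carry the topology and classification evidence
#' (`role` in hub/bottleneck/other, `degree`, `betweenness`); edge
#' attributes carry group-wise co-expression (`r_control`, `r_disease`)
#' when a co-expression table is supplied.
#'
#' @param network a [QQPPINetwork-class].
#' @param path output path.
#' @param classification optional [NodeClassification-class]; its nodes
#'   must all belong to the network.
#' @param topo optional [TopologyAttributes-class].
#' @param coexpr optional data.frame from [edgeCoexpression()].
#' @return invisibly, `path`.
#' @export
writeGraphML <- function(network, path, classification = NULL,
                         topo = NULL, coexpr = NULL) {
  g <- asIgraph(network)
  nodes <- networkNodes(network)
  if (!is.null(classification)) {
    cls <- c(hubs(classification), bottlenecks(classification))
    extra <- setdiff(cls, nodes)
    if (length(extra))
      stop("classified node(s) absent from the network: ",
           paste(extra, collapse = ", "))
    role <- rep("other", length(nodes))
    role[nodes %in% hubs(classification)] <- "hub"
    role[nodes %in% bottlenecks(classification)] <- "bottleneck"
    g <- igraph::set_vertex_attr(g, "role", value = role)
  }
  if (!is.null(topo)) {
    g <- igraph::set_vertex_attr(g, "degree",
                                 value = unname(degreeOf(topo)[nodes]))
    g <- igraph::set_vertex_attr(
      g, "betweenness", value = unname(betweennessOf(topo)[nodes]))
  }
  if (!is.null(coexpr) && nrow(coexpr)) {
    e <- networkEdges(network)
    key <- .edgeKey(e)
    ckey <- paste0(pmin(coexpr$node1, coexpr$node2), "\r",
                   pmax(coexpr$node1, coexpr$node2))
    idx <- match(key, ckey)
    g <- igraph::set_edge_attr(g, "r_control",
                               value = coexpr$rControl[idx])
    g <- igraph::set_edge_attr(g, "r_disease",
                               value = coexpr$rDisease[idx])
  }
  tryCatch(igraph::write_graph(g, path, format = "graphml"),
           error = function(e)
             stop("cannot write GraphML to ", path, ": ",
                  conditionMessage(e)))
  invisible(path)
}

#' Read a GraphML file back into a QQPPINetwork
#'
#' @param path a GraphML file written by [writeGraphML()] (or any
#'   undirected GraphML graph with a `name` vertex attribute).
#' @return a [QQPPINetwork-class].
#' @export
readGraphML <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  nodes <- igraph::vertex_attr(g, "name")
  el <- igraph::as_edgelist(g, names = TRUE)
  edges <- .canonicalEdges(el[, 1], el[, 2])
  edges$sources <- rep("graphml", nrow(edges))
  .newQQPPI(nodes, edges)
}
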