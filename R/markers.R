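# Novel marker identification: per network, the candidate set is
# (hubs union bottlenecks) minus the known-disease-gene list; the
# multiplicity total sums per-network candidate counts, and the unique
# marker set is the cross-network union with provenance. Annotation
# joins core-module membership, clique occurrence counts, matched
# complexes and curated neurotransmitter associations by gene symbol.

#' Identify previously unreported markers
#'
#' @param classifications named list of [NodeClassification-class]
#'   objects, one per network (names are network identifiers).
#' @param known character vector of known disease genes (an opaque,
#'   externally curated list).
#' @return list with elements:
#'   \describe{
#'     \item{markers}{data.frame `gene`, `networks` (";"-joined),
#'       `roles` (";"-joined `network:role`), one row per unique
#'       marker, sorted by gene.}
#'     \item{perNetwork}{named list of per-network candidate gene
#'       vectors.}
#'     \item{multiplicityTotal}{sum of per-network candidate counts.}
#'     \item{uniqueCount}{number of unique markers.}
#'     \item{sharedGenes}{markers found in more than one network.}
#'   }
#' @export
novelMarkers <- function(classifications, known = character()) {
  if (!length(classifications))
    stop("need at least one network classification")
  if (is.null(names(classifications)))
    names(classifications) <- paste0("network", seq_along(classifications))
  perNetwork <- lapply(classifications, function(cl)
    sort(setdiff(union(hubs(cl), bottlenecks(cl)), known)))
  multiplicityTotal <- sum(lengths(perNetwork))
  genes <- sort(unique(unlist(perNetwork)))
  roleOf <- function(cl, g) {
    if (g %in% hubs(cl)) "hub"
    else if (g %in% bottlenecks(cl)) "bottleneck"
    else NA_character_
  }
  rows <- lapply(genes, function(g) {
    nets <- names(perNetwork)[vapply(perNetwork, function(s) g %in% s,
                                     logical(1))]
    roles <- vapply(nets, function(nm)
      paste0(nm, ":", roleOf(classifications[[nm]], g)), "")
    data.frame(gene = g, networks = paste(nets, collapse = ";"),
               roles = paste(roles, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  markers <- do.call(rbind, rows)
  if (is.null(markers))
    markers <- data.frame(gene = character(), networks = character(),
                          roles = character(), stringsAsFactors = FALSE)
  counts <- table(unlist(perNetwork))
  list(markers = markers, perNetwork = perNetwork,
       multiplicityTotal = multiplicityTotal,
       uniqueCount = nrow(markers),
       sharedGenes = sort(names(counts)[counts > 1]))
}

#' Read a neurotransmitter association table
#'
#' TSV with a `gene` column and one column per neurotransmitter system
#' (e.g. dopaminergic, cholinergic, ...), cells `+` for association.
#'
#' @param path file path.
#' @return data.frame with columns `gene` and `neurotransmitters`
#'   (";"-joined associated system labels; empty string when none).
#' @export
readNeuroTable <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"gene" %in% colnames(df))
    stop("neurotransmitter table needs a 'gene' column")
  systems <- setdiff(colnames(df), "gene")
  assoc <- vapply(seq_len(nrow(df)), function(i)
    paste(systems[trimws(unlist(df[i, systems])) == "+"],
          collapse = ";"), "")
  data.frame(gene = trimws(df$gene), neurotransmitters = assoc,
             stringsAsFactors = FALSE)
}

#' Annotate markers with clique, complex and neurotransmitter evidence
#'
#' Each marker is flagged for core-module membership (with 3-/4-clique
#' occurrence counts summed over the supplied modules), joined with the
#' matched complexes containing it and with curated neurotransmitter
#' associations. Two prioritised subsets are reported: markers inside a
#' core functional module, and markers with at least one
#' neurotransmitter association.
#'
#' @param markerSet output of [novelMarkers()].
#' @param coreModules a [CoreModule-class] or list of them (one per
#'   network).
#' @param complexMatches data.frame from [matchComplexes()] (or a list
#'   of them), or `NULL`.
#' @param neuroTable data.frame from [readNeuroTable()], or `NULL`.
#' @return list with `annotated` (data.frame: `gene`, `networks`,
#'   `roles`, `inCoreModule`, `occurrence3`, `occurrence4`,
#'   `complexes`, `neurotransmitters`), `coreMarkers` and
#'   `neuroMarkers` (character vectors).
#' @export
annotateMarkers <- function(markerSet, coreModules,
                            complexMatches = NULL, neuroTable = NULL) {
  markers <- markerSet$markers
  if (is(coreModules, "CoreModule")) coreModules <- list(coreModules)
  if (is.data.frame(complexMatches))
    complexMatches <- list(complexMatches)
  occ3 <- setNames(numeric(nrow(markers)), markers$gene)
  occ4 <- occ3
  inCore <- setNames(logical(nrow(markers)), markers$gene)
  for (cm in coreModules) {
    hit <- intersect(markers$gene, cm@nodes)
    inCore[hit] <- TRUE
    occ3[hit] <- occ3[hit] + cm@occurrence3[hit]
    occ4[hit] <- occ4[hit] + cm@occurrence4[hit]
  }
  cpx <- setNames(rep("", nrow(markers)), markers$gene)
  for (mm in complexMatches) {
    if (is.null(mm) || !nrow(mm)) next
    for (i in seq_len(nrow(mm))) {
      members <- strsplit(mm$matched[i], ";", fixed = TRUE)[[1]]
      hit <- intersect(markers$gene, members)
      cpx[hit] <- ifelse(nzchar(cpx[hit]),
                         paste(cpx[hit], mm$id[i], sep = ";"),
                         mm$id[i])
    }
  }
  neuro <- setNames(rep("", nrow(markers)), markers$gene)
  if (!is.null(neuroTable) && nrow(neuroTable)) {
    unknown <- setdiff(neuroTable$gene, markers$gene)
    if (length(unknown))
      message("ignoring neurotransmitter rows for non-marker gene(s): ",
              paste(unknown, collapse = ", "))
    hit <- intersect(neuroTable$gene, markers$gene)
    neuro[hit] <- neuroTable$neurotransmitters[match(hit,
                                                     neuroTable$gene)]
  }
  annotated <- cbind(markers,
                     data.frame(inCoreModule = unname(inCore),
                                occurrence3 = unname(occ3),
                                occurrence4 = unname(occ4),
                                complexes = unname(cpx),
                                neurotransmitters = unname(neuro),
                                stringsAsFactors = FALSE))
  list(annotated = annotated,
       coreMarkers = markers$gene[unname(inCore)],
       neuroMarkers = markers$gene[nzchar(unname(neuro))])
}
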