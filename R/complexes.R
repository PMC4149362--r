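# Complex matching: report every catalog complex containing at least
# `minQuery` query proteins (the query is typically the set of
# clique-forming proteins).

#' Match query proteins against a complex catalog
#'
#' @param query character vector of gene symbols (typically all proteins
#'   occurring in any 3- or 4-clique; see [cliqueProteins()]).
#' @param catalog a [ComplexCatalog-class].
#' @param minQuery minimum number of query proteins a complex must
#'   contain to be reported (>= 1).
#' @return data.frame with columns `id`, `name`, `nMembers`,
#'   `nMatched`, `matched` (";"-joined sorted query members), sorted by
#'   `nMatched` descending, then `id`.
#' @export
matchComplexes <- function(query, catalog, minQuery = 5) {
  stopifnot(minQuery >= 1)
  query <- unique(query)
  info <- termInfo(catalog)
  members <- geneSets(catalog)
  hit <- lapply(seq_len(nrow(info)), function(i) {
    matched <- sort(intersect(members[[i]], query))
    if (length(matched) < minQuery) return(NULL)
    data.frame(id = info$id[i], name = info$name[i],
               nMembers = length(members[[i]]),
               nMatched = length(matched),
               matched = paste(matched, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, hit)
  if (is.null(out))
    out <- data.frame(id = character(), name = character(),
                      nMembers = integer(), nMatched = integer(),
                      matched = character(), stringsAsFactors = FALSE)
  out <- out[order(-out$nMatched, out$id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Proteins occurring in any clique
#'
#' @param cliques3,cliques4 lists from [enumerateKCliques()].
#' @return sorted character vector of clique-forming proteins.
#' @export
cliqueProteins <- function(cliques3, cliques4 = list()) {
  sort(unique(as.character(unlist(c(cliques3, cliques4)))))
}
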