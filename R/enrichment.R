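# Gene-set over-representation. For each term, the one-sided upper
# hypergeometric tail P(X >= k) with population N (background), K
# successes (background genes in the term), and n draws (query size).
# Selection keeps query genes annotated to any term with raw p below the
# threshold in the requested namespace (no adjustment by default,
# Benjamini-Hochberg available).

#' Hypergeometric over-representation test per term
#'
#' @param query character vector of query genes (must be a subset of
#'   `background`).
#' @param background character vector: the gene universe (typically all
#'   genes in the expression dataset after probe collapse).
#' @param annotation a [TermAnnotation-class]; term gene sets are
#'   intersected with the background before testing.
#' @return data.frame with columns `id`, `name`, `namespace`, `k`
#'   (query genes in term), `K` (background genes in term), `n` (query
#'   size), `N` (background size), `p`.
#' @export
overRepresentation <- function(query, background, annotation) {
  query <- unique(query); background <- unique(background)
  offenders <- setdiff(query, background)
  if (length(offenders))
    stop("query gene(s) absent from background: ",
         paste(head(offenders, 10), collapse = ", "),
         if (length(offenders) > 10) ", ...")
  info <- termInfo(annotation)
  sets <- geneSets(annotation)
  N <- length(background); n <- length(query)
  rec <- lapply(seq_len(nrow(info)), function(i) {
    members <- intersect(sets[[i]], background)
    K <- length(members)
    k <- length(intersect(members, query))
    # upper tail P(X >= k)
    p <- if (k == 0) 1 else phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(id = info$id[i], name = info$name[i],
               namespace = info$namespace[i],
               k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rec)
  if (is.null(out))
    out <- data.frame(id = character(), name = character(),
                      namespace = character(), k = integer(),
                      K = integer(), n = integer(), N = integer(),
                      p = numeric(), stringsAsFactors = FALSE)
  out[order(out$p, out$id), , drop = FALSE]
}

#' Select query genes annotated to significant terms
#'
#' The union of (query intersect term members) over all terms with
#' p (or BH-adjusted p) below `alpha` in the requested namespace. This
#' is the filtered query gene set handed to network construction.
#'
#' @param records output of [overRepresentation()].
#' @param annotation the [TermAnnotation-class] the records were
#'   computed from.
#' @param query the query gene set.
#' @param alpha significance threshold on the raw (or adjusted) p.
#' @param namespace term namespace to restrict to (e.g. `"BP"`);
#'   `NULL` keeps all namespaces.
#' @param adjust `"none"` (default, mirrors a raw p < 0.05 rule) or
#'   `"BH"` for Benjamini-Hochberg.
#' @return character vector (sorted, unique) of selected genes.
#' @export
selectGenesInSignificantTerms <- function(records, annotation, query,
                                          alpha = 0.05,
                                          namespace = "BP",
                                          adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (!is.null(namespace))
    records <- records[records$namespace == namespace, , drop = FALSE]
  p <- records$p
  if (adjust == "BH") p <- stats::p.adjust(p, method = "BH")
  sig <- records$id[p < alpha]
  if (!length(sig)) return(character())
  sets <- geneSets(annotation)[as.character(sig)]
  sort(unique(unlist(lapply(sets, intersect, x = query))))
}
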