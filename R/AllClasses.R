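#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom stats cor mad median pt phyper quantile rnorm sd setNames
#' @importFrom utils combn read.delim write.table head
NULL

#' ExpressionDataset: a two-group expression matrix
#'
#' A \linkS4class{SummarizedExperiment} holding a log2 expression matrix
#' (genes x samples) in the \code{"exprs"} assay, with a mandatory
#' \code{group} column in \code{colData} taking the values \code{"control"}
#' and \code{"disease"}. All differential-expression and co-expression
#' statistics in the package operate on this container.
#'
#' @seealso [ExpressionDataset()] for the constructor, [readExpression()]
#'   to build one from TSV files.
#' @export
setClass("ExpressionDataset", contains = "SummarizedExperiment")

setValidity("ExpressionDataset", function(object) {
  msg <- character()
  if (!"exprs" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'exprs' is required")
  cd <- SummarizedExperiment::colData(object)
  if (!"group" %in% colnames(cd)) {
    msg <- c(msg, "colData must contain a 'group' column")
  } else {
    g <- as.character(cd$group)
    bad <- setdiff(unique(g), c("control", "disease"))
    if (length(bad))
      msg <- c(msg, paste0("unknown group label(s): ",
                           paste(bad, collapse = ", ")))
    if (!all(c("control", "disease") %in% g))
      msg <- c(msg, "need at least one sample in each of control and disease")
  }
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "gene identifiers must be unique (collapse probes first)")
  if (length(msg)) msg else TRUE
})

#' Interactome: an undirected protein-protein interaction edge list
#'
#' Stores deduplicated unordered gene-symbol pairs with a per-edge source
#' tag recording which database export contributed the interaction.
#' Self-interactions are never stored.
#'
#' @slot edges data.frame with character columns \code{node1}, \code{node2}
#'   (canonical order: \code{node1 < node2}) and \code{source}.
#' @seealso [Interactome()], [readSif()]
#' @export
setClass("Interactome", representation(edges = "data.frame"))

setValidity("Interactome", function(object) {
  e <- object@edges
  if (!all(c("node1", "node2", "source") %in% colnames(e)))
    return("edges must have columns node1, node2, source")
  if (nrow(e)) {
    if (any(e$node1 == e$node2)) return("self-interactions are not allowed")
    if (any(e$node1 > e$node2)) return("edges must be in canonical order")
    if (anyDuplicated(paste(e$node1, e$node2)))
      return("duplicate edges are not allowed")
  }
  TRUE
})

#' QQPPINetwork: a query-query PPI network
#'
#' A simple undirected graph induced on a query gene set: every node is a
#' query protein and every edge an interactome interaction between two
#' query proteins. Each protein occurs exactly once. Per-edge provenance
#' records the interactome source tags that support the edge.
#'
#' @slot nodes character vector of gene symbols (unique).
#' @slot edges data.frame with columns \code{node1}, \code{node2}
#'   (canonical order) and \code{sources} (";"-joined tags).
#' @seealso [buildQQPPI()], [mergeNetworks()]
#' @export
setClass("QQPPINetwork", representation(nodes = "character",
                                        edges = "data.frame"))

setValidity("QQPPINetwork", function(object) {
  e <- object@edges
  if (!all(c("node1", "node2", "sources") %in% colnames(e)))
    return("edges must have columns node1, node2, sources")
  if (anyDuplicated(object@nodes)) return("nodes must be unique")
  if (nrow(e)) {
    if (any(e$node1 == e$node2)) return("self-loops are not allowed")
    if (any(e$node1 > e$node2)) return("edges must be in canonical order")
    if (anyDuplicated(paste(e$node1, e$node2)))
      return("parallel edges are not allowed")
    if (!all(c(e$node1, e$node2) %in% object@nodes))
      return("every edge endpoint must be a node")
  }
  TRUE
})

#' ComplexCatalog: a protein-complex membership catalog
#'
#' @slot info data.frame with character columns \code{id}, \code{name}.
#' @slot members named list (by id) of character gene vectors.
#' @seealso [readComplexCatalog()], [matchComplexes()]
#' @export
setClass("ComplexCatalog", representation(info = "data.frame",
                                          members = "list"))

setValidity("ComplexCatalog", function(object) {
  if (!all(c("id", "name") %in% colnames(object@info)))
    return("info must have columns id, name")
  if (anyDuplicated(object@info$id)) return("complex ids must be unique")
  if (!identical(names(object@members), as.character(object@info$id)))
    return("members must be named by info$id, in the same order")
  if (any(lengths(object@members) == 0))
    return("member sets must be non-empty")
  TRUE
})

#' TermAnnotation: term-to-gene-set annotation (GMT-style)
#'
#' @slot info data.frame with character columns \code{id}, \code{name},
#'   \code{namespace}.
#' @slot genes named list (by term id) of character gene vectors.
#' @seealso [readGmt()], [overRepresentation()]
#' @export
setClass("TermAnnotation", representation(info = "data.frame",
                                          genes = "list"))

setValidity("TermAnnotation", function(object) {
  if (!all(c("id", "name", "namespace") %in% colnames(object@info)))
    return("info must have columns id, name, namespace")
  if (anyDuplicated(object@info$id)) return("term ids must be unique")
  if (!identical(names(object@genes), as.character(object@info$id)))
    return("genes must be named by info$id, in the same order")
  if (any(lengths(object@genes) == 0)) return("gene sets must be non-empty")
  TRUE
})

#' TopologyAttributes: per-node degree and betweenness
#'
#' Degree is the number of incident edges. Betweenness is the Brandes
#' shortest-path centrality on the unweighted undirected graph: each
#' unordered node pair is counted once, endpoints are excluded, and no
#' normalisation is applied.
#'
#' @slot degree named integer-valued numeric vector.
#' @slot betweenness named numeric vector.
#' @seealso [computeTopology()]
#' @export
setClass("TopologyAttributes", representation(degree = "numeric",
                                              betweenness = "numeric"))

setValidity("TopologyAttributes", function(object) {
  if (!identical(names(object@degree), names(object@betweenness)))
    return("degree and betweenness must be named identically")
  if (length(object@degree) && any(object@degree < 0))
    return("degrees must be non-negative")
  if (length(object@betweenness) && any(object@betweenness < -1e-9))
    return("betweenness must be non-negative")
  TRUE
})

#' HubCutoff: the hub degree cutoff M + 2S
#'
#' Mean (M) and standard deviation (S) of the degree distribution, the
#' hub cutoff M + 2S, and its nearest-integer rounding as printed in
#' summary tables. Classification always uses the unrounded cutoff
#' (degrees are integers, so for example degree >= 11.8 iff degree >= 12).
#'
#' @slot meanDegree,sdDegree,cutoff,roundedCutoff numeric scalars.
#' @slot sdMode "sample" (n-1 denominator) or "population".
#' @seealso [hubCutoff()], [classifyHubs()]
#' @export
setClass("HubCutoff", representation(meanDegree = "numeric",
                                     sdDegree = "numeric",
                                     cutoff = "numeric",
                                     roundedCutoff = "numeric",
                                     sdMode = "character"))

setValidity("HubCutoff", function(object) {
  if (object@sdDegree < 0) return("sdDegree must be non-negative")
  if (abs(object@cutoff - (object@meanDegree + 2 * object@sdDegree)) > 1e-9)
    return("cutoff must equal meanDegree + 2 * sdDegree")
  if (object@roundedCutoff != round(object@cutoff))
    return("roundedCutoff must be round(cutoff)")
  TRUE
})

#' NodeClassification: hubs and bottlenecks of a network
#'
#' Hubs are nodes with degree at least the hub cutoff. Bottlenecks are
#' non-hub nodes in the top half of the betweenness distribution with at
#' least two hub neighbours. The two sets are disjoint by construction.
#'
#' @slot hubs,bottlenecks character vectors of gene symbols.
#' @slot evidence data.frame (node, degree, betweenness, hubNeighbors, role).
#' @slot cutoff the \linkS4class{HubCutoff} used.
#' @seealso [classifyNodes()]
#' @export
setClass("NodeClassification", representation(hubs = "character",
                                              bottlenecks = "character",
                                              evidence = "data.frame",
                                              cutoff = "HubCutoff"))

setValidity("NodeClassification", function(object) {
  if (length(intersect(object@hubs, object@bottlenecks)))
    return("hubs and bottlenecks must be disjoint")
  need <- c("node", "degree", "betweenness", "hubNeighbors", "role")
  if (!all(need %in% colnames(object@evidence)))
    return(paste("evidence must have columns", paste(need, collapse = ", ")))
  TRUE
})

#' SamResult: Significance Analysis of Microarrays output
#'
#' Per-gene relative difference d = (mean disease - mean control) /
#' (s + s0), the pooled gene-specific scatter s, the exchangeability
#' constant s0, expected order statistics of d under label permutations,
#' and a calibrated delta/FDR table. Genes called at the chosen delta
#' carry an up- (UR) or down-regulated (DR) direction.
#'
#' @slot d,s named numeric vectors (per gene).
#' @slot s0 numeric scalar.
#' @slot expectedD numeric vector of expected order statistics (ascending).
#' @slot deltaTable data.frame (delta, called, medianFalse, fdr).
#' @slot called character vector of called genes at \code{delta}.
#' @slot direction named character vector ("UR"/"DR") for called genes.
#' @slot delta,fdr numeric scalars: the calibrated threshold and its FDR.
#' @slot excluded genes dropped before calling (zero scatter in both groups).
#' @slot foldAdmissible genes passing the fold-change filter (all tested
#'   genes when no filter is configured).
#' @slot config list of run parameters (nPermutations, s0Policy,
#'   foldChange, seed).
#' @seealso [samAnalysis()], [selectDeSam()]
#' @export
setClass("SamResult", representation(d = "numeric", s = "numeric",
                                     s0 = "numeric", expectedD = "numeric",
                                     deltaTable = "data.frame",
                                     called = "character",
                                     direction = "character",
                                     delta = "numeric", fdr = "numeric",
                                     excluded = "character",
                                     foldAdmissible = "character",
                                     config = "list"))

setValidity("SamResult", function(object) {
  if (!all(object@called %in% names(object@d)))
    return("called genes must be a subset of the tested genes")
  if (length(setdiff(object@called, names(object@direction))) ||
      length(setdiff(names(object@direction), object@called)))
    return("every called gene must have a direction")
  if (length(object@direction) &&
      !all(object@direction %in% c("UR", "DR")))
    return("directions must be UR or DR")
  if (length(object@fdr) && object@fdr < 0) return("fdr must be >= 0")
  TRUE
})

#' CoreModule: the union of 3- and 4-cliques
#'
#' The core functional module of a network: every node and edge that
#' participates in at least one 3- or 4-clique, with per-node occurrence
#' counts in each clique size.
#'
#' @slot nodes character vector.
#' @slot edges data.frame (node1, node2), canonical order.
#' @slot occurrence3,occurrence4 named numeric count vectors over nodes.
#' @seealso [coreFunctionalModule()], [enumerateKCliques()]
#' @export
setClass("CoreModule", representation(nodes = "character",
                                      edges = "data.frame",
                                      occurrence3 = "numeric",
                                      occurrence4 = "numeric"))

setValidity("CoreModule", function(object) {
  if (!identical(names(object@occurrence3), object@nodes) ||
      !identical(names(object@occurrence4), object@nodes))
    return("occurrence counts must be named by nodes, in order")
  if (nrow(object@edges) &&
      !all(c(object@edges$node1, object@edges$node2) %in% object@nodes))
    return("edge endpoints must be module nodes")
  TRUE
})

#' SyntheticSpec: parameters of the synthetic-data generators
#'
#' One object describes a full synthetic study: a two-group log2
#' expression matrix with planted up/down-regulated genes, an interactome
#' (scale-free, configuration-model, or planted cliques/hubs over an
#' Erdos-Renyi background), a complex catalog and a term annotation, all
#' reproducible from \code{seed}.
#'
#' @seealso [syntheticSpec()] for the constructor with defaults and
#'   validation, and the generators [generateExpression()],
#'   [generateInteractome()], [generateComplexCatalog()],
#'   [generateTermAnnotation()].
#' @export
setClass("SyntheticSpec", representation(
  nGenes = "numeric", nControl = "numeric", nDisease = "numeric",
  deFraction = "numeric", upFraction = "numeric",
  effectSize = "numeric", noiseSd = "numeric",
  interactomeModel = "character", nProteins = "numeric",
  edgesPerNode = "numeric", nPlantedCliques = "numeric",
  plantedCliqueSizes = "numeric", nPlantedHubs = "numeric",
  nComplexes = "numeric", complexSizeRange = "numeric",
  nTerms = "numeric", probesPerGene = "numeric", seed = "numeric"))

setValidity("SyntheticSpec", function(object) {
  chk <- function(cond, what) if (!cond) what else NULL
  msg <- c(
    chk(object@nGenes >= 1, "nGenes must be >= 1"),
    chk(object@nControl >= 3, "nControl must be >= 3"),
    chk(object@nDisease >= 3, "nDisease must be >= 3"),
    chk(object@deFraction >= 0 && object@deFraction <= 1,
        "deFraction must be in [0, 1]"),
    chk(object@upFraction >= 0 && object@upFraction <= 1,
        "upFraction must be in [0, 1]"),
    chk(object@noiseSd > 0, "noiseSd must be > 0"),
    chk(object@interactomeModel %in%
          c("scale_free", "configuration", "planted"),
        "interactomeModel must be scale_free, configuration or planted"),
    chk(object@nProteins >= 1, "nProteins must be >= 1"),
    chk(object@edgesPerNode >= 1, "edgesPerNode must be >= 1"),
    chk(object@nPlantedCliques >= 0, "nPlantedCliques must be >= 0"),
    chk(all(object@plantedCliqueSizes %in% c(3, 4)),
        "plantedCliqueSizes must be 3 or 4"),
    chk(object@nPlantedHubs >= 0, "nPlantedHubs must be >= 0"),
    chk(object@nComplexes >= 0, "nComplexes must be >= 0"),
    chk(length(object@complexSizeRange) == 2 &&
          object@complexSizeRange[1] >= 1 &&
          object@complexSizeRange[1] <= object@complexSizeRange[2],
        "complexSizeRange must be (min, max) with 1 <= min <= max"),
    chk(object@nTerms >= 0, "nTerms must be >= 0"),
    chk(object@probesPerGene >= 1, "probesPerGene must be >= 1"),
    chk(length(object@seed) == 1 && is.finite(object@seed),
        "seed must be a single finite integer"))
  if (object@nPlantedCliques > 0 &&
      object@nPlantedCliques * max(object@plantedCliqueSizes) >
        object@nProteins)
    msg <- c(msg, "nPlantedCliques * max(plantedCliqueSizes) exceeds nProteins")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' GroundTruth: planted structure behind a synthetic dataset
#'
#' @slot deGenesUp,deGenesDown planted up-/down-regulated gene sets
#'   (disjoint).
#' @slot plantedCliques list of gene vectors fully connected in the
#'   generated interactome.
#' @slot plantedHubGenes genes wired to exceed the hub degree cutoff.
#' @export
setClass("GroundTruth", representation(deGenesUp = "character",
                                       deGenesDown = "character",
                                       plantedCliques = "list",
                                       plantedHubGenes = "character"))

setValidity("GroundTruth", function(object) {
  if (length(intersect(object@deGenesUp, object@deGenesDown)))
    return("deGenesUp and deGenesDown must be disjoint")
  TRUE
})
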