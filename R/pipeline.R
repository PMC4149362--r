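# End-to-end orchestration. Two parallel branches mirror the study
# design: a t-test-derived query set and a SAM-derived query set each
# produce a QQPPI network (built per interactome, then merged); the
# branches stay separate through topology, cliques, complexes and
# co-expression, and are combined only at the marker stage.

#' Assemble a pipeline configuration
#'
#' @param expression,phenotype paths to the expression matrix and
#'   phenotype TSV.
#' @param interactomes character vector of SIF paths (one or more).
#' @param annotation GMT path, or `NULL` to skip the enrichment filter.
#' @param catalog complex-catalog TSV path, or `NULL` to skip complex
#'   matching.
#' @param known path to the known-disease-gene list, or `NULL`.
#' @param neuro path to the neurotransmitter association TSV, or `NULL`.
#' @param outDir output directory for run artifacts.
#' @param alpha t-test selection threshold (raw two-sided P).
#' @param fdrTarget SAM FDR target.
#' @param nPermutations SAM label permutations.
#' @param enrichAlpha over-representation threshold.
#' @param namespace annotation namespace for the enrichment filter.
#' @param sdMode degree SD mode for the hub cutoff.
#' @param minQuery named numeric: minimum query proteins per complex,
#'   per branch.
#' @param mergeMode `"union"` or `"intersection"` for network merging.
#' @param maximalOnly count only maximal cliques?
#' @param collapse probe-collapse policy for [readExpression()].
#' @param seed integer seed for every stochastic stage.
#' @return a list of class `"PipelineConfig"`.
#' @export
pipelineConfig <- function(expression, phenotype, interactomes,
                           annotation = NULL, catalog = NULL,
                           known = NULL, neuro = NULL,
                           outDir = tempfile("qqppi_run"),
                           alpha = 0.001, fdrTarget = 0.0019,
                           nPermutations = 200, enrichAlpha = 0.05,
                           namespace = "BP", sdMode = "sample",
                           minQuery = c(ttest = 5, sam = 4),
                           mergeMode = "union", maximalOnly = FALSE,
                           collapse = "mean", seed = 1) {
  structure(list(expression = expression, phenotype = phenotype,
                 interactomes = interactomes, annotation = annotation,
                 catalog = catalog, known = known, neuro = neuro,
                 outDir = outDir, alpha = alpha, fdrTarget = fdrTarget,
                 nPermutations = nPermutations,
                 enrichAlpha = enrichAlpha, namespace = namespace,
                 sdMode = sdMode, minQuery = minQuery,
                 mergeMode = mergeMode, maximalOnly = maximalOnly,
                 collapse = collapse, seed = seed),
            class = "PipelineConfig")
}

#' Run the full marker-discovery pipeline
#'
#' Stage order: differential-expression selection (t-test and SAM
#' branches in parallel), over-representation filter, QQPPI
#' construction and merging per branch, topology and hub/bottleneck
#' classification, 3-/4-clique enumeration and core module, complex
#' matching, per-edge co-expression, and cross-branch novel-marker
#' identification. All stage outputs are written under
#' `config$outDir` together with a `manifest.json` recording inputs,
#' parameters and stage counts; a failing stage aborts with its name
#' and leaves a `FAILED` marker file.
#'
#' @param config a `"PipelineConfig"` list from [pipelineConfig()].
#' @return invisibly, a list with the per-branch results (`branches`),
#'   the marker report (`markers`), and the manifest.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  required <- c(config$expression, config$phenotype, config$interactomes,
                config$annotation, config$catalog, config$known,
                config$neuro)
  for (p in required)
    if (!file.exists(p)) stop("input path does not exist: ", p)
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  failedFlag <- file.path(config$outDir, "FAILED")
  if (file.exists(failedFlag)) unlink(failedFlag)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(paste0(name, ": ", conditionMessage(e)), failedFlag)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  counts <- list()

  dataset <- stage("read_expression",
                   readExpression(config$expression, config$phenotype,
                                  collapse = config$collapse))
  background <- rownames(dataset)
  interactomes <- stage("read_interactomes",
                        lapply(config$interactomes, readSif))
  annotation <- if (!is.null(config$annotation))
    stage("read_annotation", readGmt(config$annotation))
  catalog <- if (!is.null(config$catalog))
    stage("read_catalog", readComplexCatalog(config$catalog))
  known <- if (!is.null(config$known))
    stage("read_known", readGeneList(config$known)) else character()
  neuro <- if (!is.null(config$neuro))
    stage("read_neuro", readNeuroTable(config$neuro))

  deT <- stage("de_ttest", selectDeTtest(tTest(dataset),
                                         alpha = config$alpha))
  sam <- stage("de_sam", samAnalysis(dataset,
                                     nPermutations = config$nPermutations,
                                     seed = config$seed,
                                     fdrTarget = config$fdrTarget))
  deS <- sam@called
  counts$deGenes <- c(ttest = length(deT), sam = length(deS))

  queries <- list(ttest = deT, sam = deS)
  if (!is.null(annotation)) {
    queries <- stage("enrichment_filter", lapply(queries, function(q) {
      if (!length(q)) return(character())
      rec <- overRepresentation(q, background, annotation)
      selectGenesInSignificantTerms(rec, annotation, q,
                                    alpha = config$enrichAlpha,
                                    namespace = config$namespace)
    }))
  }
  counts$queryGenes <- lengths(queries)

  branches <- list()
  for (branch in names(queries)) {
    q <- queries[[branch]]
    if (!length(q)) {
      branches[[branch]] <- NULL
      next
    }
    nets <- stage(paste0("network_", branch),
                  lapply(interactomes, function(i) buildQQPPI(q, i)))
    net <- stage(paste0("merge_", branch),
                 Reduce(function(a, b)
                   mergeNetworks(a, b, mode = config$mergeMode), nets))
    topo <- computeTopology(net)
    cls <- stage(paste0("topology_", branch),
                 classifyNodes(net, sdMode = config$sdMode, topo = topo))
    c3 <- stage(paste0("cliques_", branch),
                enumerateKCliques(net, 3,
                                  maximalOnly = config$maximalOnly))
    c4 <- enumerateKCliques(net, 4, maximalOnly = config$maximalOnly)
    core <- coreFunctionalModule(c3, c4, net)
    matches <- if (!is.null(catalog))
      stage(paste0("complexes_", branch),
            matchComplexes(cliqueProteins(c3, c4), catalog,
                           minQuery = config$minQuery[[branch]]))
    coexpr <- stage(paste0("coexpression_", branch),
                    edgeCoexpression(net, dataset))
    cpxCo <- if (!is.null(matches) && nrow(matches))
      complexCoexpression(matches, networkEdges(net), dataset)
    branches[[branch]] <- list(network = net, topo = topo,
                               classification = cls,
                               cliques3 = c3, cliques4 = c4,
                               core = core, complexes = matches,
                               coexpression = coexpr,
                               complexCoexpression = cpxCo)
    counts[[paste0(branch, "_network")]] <-
      c(nodes = length(networkNodes(net)),
        edges = nrow(networkEdges(net)),
        hubs = length(hubs(cls)), bottlenecks = length(bottlenecks(cls)),
        cliques3 = length(c3), cliques4 = length(c4))
  }
  if (!length(branches)) stop("no branch produced a non-empty network")

  classifications <- lapply(branches, `[[`, "classification")
  markerSet <- stage("markers", novelMarkers(classifications, known))
  annot <- stage("annotate_markers",
                 annotateMarkers(markerSet,
                                 lapply(branches, `[[`, "core"),
                                 lapply(branches, `[[`, "complexes"),
                                 neuro))
  counts$markers <- c(multiplicity = markerSet$multiplicityTotal,
                      unique = markerSet$uniqueCount,
                      core = length(annot$coreMarkers),
                      neuro = length(annot$neuroMarkers))

  out <- function(...) file.path(config$outDir, ...)
  for (branch in names(branches)) {
    b <- branches[[branch]]
    writeSif(b$network, out(paste0("network_", branch, ".sif")))
    writeGraphML(b$network, out(paste0("network_", branch, ".graphml")),
                 classification = b$classification, topo = b$topo,
                 coexpr = b$coexpression)
    write.table(b$classification@evidence,
                out(paste0("topology_", branch, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    .writeReportTsv(b$coexpression,
                    out(paste0("coexpression_", branch, ".tsv")))
    if (!is.null(b$complexes))
      write.table(b$complexes, out(paste0("complexes_", branch, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write.table(annot$annotated, out("markers.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  manifest <- list(
    inputs = config[c("expression", "phenotype", "interactomes",
                      "annotation", "catalog", "known", "neuro")],
    parameters = config[c("alpha", "fdrTarget", "nPermutations",
                          "enrichAlpha", "namespace", "sdMode",
                          "minQuery", "mergeMode", "maximalOnly",
                          "collapse", "seed")],
    version = as.character(utils::packageVersion("qqppi")),
    counts = counts)
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(branches = branches, markers = annot,
                 markerSet = markerSet, manifest = manifest,
                 outDir = config$outDir))
}

# report TSVs print floats with 6 decimals (table convention)
.writeReportTsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.6f", x))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
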