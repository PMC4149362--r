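# Synthetic-data generators. They emulate the statistical shape of the
# inputs the pipeline consumes: a gcRMA-style log2 expression matrix with
# two small sample groups and planted up/down-regulated genes, database
# export style interactome edge lists, a complex catalog and a term
# annotation, each deterministic in the spec seed and accompanied by
# ground truth for recovery tests.

#' Create a SyntheticSpec
#'
#' Defaults describe the study conditions the package is calibrated
#' against: 2000 genes measured on 15 control and 24 disease samples
#' (log2 scale), a planted differential-expression fraction of 10% with a
#' mean log2 shift of 2 against within-group noise SD 0.5, and a 500-node
#' interactome with two edges per node.
#'
#' @param nGenes,nControl,nDisease matrix dimensions (>= 3 samples per
#'   group; Pearson correlation needs at least 3).
#' @param deFraction fraction of genes differentially expressed.
#' @param upFraction fraction of DE genes shifted up in disease.
#' @param effectSize mean log2 shift of DE genes in the disease group.
#' @param noiseSd within-group standard deviation (log2 units).
#' @param interactomeModel `"scale_free"` (preferential attachment),
#'   `"configuration"` (heavy-tailed degree sequence), or `"planted"`
#'   (Erdos-Renyi background with planted cliques and hubs).
#' @param nProteins,edgesPerNode interactome size and density.
#' @param nPlantedCliques,plantedCliqueSizes,nPlantedHubs planted
#'   structure (used by the `"planted"` model).
#' @param nComplexes,complexSizeRange complex catalog shape.
#' @param nTerms number of annotation terms.
#' @param probesPerGene rows written per gene symbol by
#'   [writeSyntheticBundle()], to exercise probe collapsing on read.
#' @param seed integer seed; identical spec + seed gives identical output.
#' @return a validated [SyntheticSpec-class].
#' @export
syntheticSpec <- function(nGenes = 2000, nControl = 15, nDisease = 24,
                          deFraction = 0.1, upFraction = 0.2,
                          effectSize = 2, noiseSd = 0.5,
                          interactomeModel = "scale_free",
                          nProteins = 500, edgesPerNode = 2,
                          nPlantedCliques = 4,
                          plantedCliqueSizes = c(3, 4),
                          nPlantedHubs = 5,
                          nComplexes = 20, complexSizeRange = c(4, 10),
                          nTerms = 50, probesPerGene = 1, seed = 1) {
  obj <- new("SyntheticSpec",
             nGenes = nGenes, nControl = nControl, nDisease = nDisease,
             deFraction = deFraction, upFraction = upFraction,
             effectSize = effectSize, noiseSd = noiseSd,
             interactomeModel = interactomeModel, nProteins = nProteins,
             edgesPerNode = edgesPerNode,
             nPlantedCliques = nPlantedCliques,
             plantedCliqueSizes = plantedCliqueSizes,
             nPlantedHubs = nPlantedHubs, nComplexes = nComplexes,
             complexSizeRange = complexSizeRange, nTerms = nTerms,
             probesPerGene = probesPerGene, seed = seed)
  msg <- validObject(obj, test = TRUE)
  if (is.character(msg)) stop("invalid SyntheticSpec: ", msg)
  obj
}

# Shared deterministic layout: gene names, DE gene indices and directions,
# and the interactome node set. Both the expression and the interactome
# generator derive it identically so planted cliques/hubs can be placed on
# differentially expressed genes.
.syntheticLayout <- function(spec) {
  genes <- sprintf("G%05d", seq_len(spec@nGenes))
  withSeed(spec@seed, {
    nDe <- round(spec@nGenes * spec@deFraction)
    deIdx <- sort(sample.int(spec@nGenes, nDe))
    nUp <- round(nDe * spec@upFraction)
    upIdx <- if (nDe) sort(sample(deIdx, nUp)) else integer()
    nodeIdx <- sort(sample.int(spec@nGenes, min(spec@nProteins, spec@nGenes)))
  })
  list(genes = genes,
       deUp = genes[upIdx],
       deDown = genes[setdiff(deIdx, upIdx)],
       nodes = genes[nodeIdx])
}

# sample() without the scalar-x surprise
.safeSample <- function(x, size = length(x)) x[sample.int(length(x), size)]

# evaluate `expr` under a temporary RNG state seeded with `seed`
withSeed <- function(seed, expr) {
  hadSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (hadSeed) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (hadSeed) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Generate a synthetic two-group expression dataset
#'
#' Non-DE genes share a common mean between groups; DE genes are shifted
#' by +/- `effectSize` in the disease group; every cell receives
#' independent Normal(0, `noiseSd`) noise. Baseline log2 means are drawn
#' uniformly from \[4, 10\], the dynamic range typical of gcRMA output.
#'
#' @param spec a [SyntheticSpec-class].
#' @return list with elements `dataset` ([ExpressionDataset-class]) and
#'   `truth` ([GroundTruth-class]).
#' @examples
#' sim <- generateExpression(syntheticSpec(nGenes = 50, seed = 3))
#' dim(exprsValues(sim$dataset))
#' @export
generateExpression <- function(spec) {
  stopifnot(is(spec, "SyntheticSpec"))
  lay <- .syntheticLayout(spec)
  nS <- spec@nControl + spec@nDisease
  samples <- c(sprintf("C%02d", seq_len(spec@nControl)),
               sprintf("D%02d", seq_len(spec@nDisease)))
  group <- rep(c("control", "disease"), c(spec@nControl, spec@nDisease))
  withSeed(spec@seed + 1L, {
    base <- stats::runif(spec@nGenes, 4, 10)
    shift <- numeric(spec@nGenes)
    names(shift) <- lay$genes
    shift[lay$deUp] <- spec@effectSize
    shift[lay$deDown] <- -spec@effectSize
    m <- matrix(stats::rnorm(spec@nGenes * nS, sd = spec@noiseSd),
                spec@nGenes, nS)
  })
  m <- m + base
  m[, group == "disease"] <- m[, group == "disease"] + shift
  dimnames(m) <- list(lay$genes, samples)
  truth <- new("GroundTruth", deGenesUp = lay$deUp,
               deGenesDown = lay$deDown,
               plantedCliques = list(), plantedHubGenes = character())
  list(dataset = ExpressionDataset(m, group), truth = truth)
}

#' Generate a synthetic interactome
#'
#' Node symbols are drawn from the same gene universe as
#' [generateExpression()] under the same seed, so downstream query sets
#' intersect the interactome. Three models are available: preferential
#' attachment (`scale_free`), a heavy-tailed configuration model
#' (`configuration`), and `planted`, which overlays fully connected
#' cliques and high-degree hub nodes on an Erdos-Renyi background.
#' Planted cliques and hubs are placed on planted DE genes whenever
#' enough of them fall inside the node set.
#'
#' @param spec a [SyntheticSpec-class].
#' @return list with elements `interactome` ([Interactome-class]) and
#'   `truth` ([GroundTruth-class]) carrying planted cliques and hubs.
#' @export
generateInteractome <- function(spec) {
  stopifnot(is(spec, "SyntheticSpec"))
  lay <- .syntheticLayout(spec)
  nodes <- lay$nodes
  n <- length(nodes)
  plantedCliques <- list()
  plantedHubs <- character()
  g <- withSeed(spec@seed + 2L, {
    if (spec@interactomeModel == "scale_free") {
      g <- igraph::sample_pa(n, m = spec@edgesPerNode, directed = FALSE)
    } else if (spec@interactomeModel == "configuration") {
      # Zipf-style degrees (exponent ~2.5) truncated at sqrt(n)
      u <- stats::runif(n)
      deg <- pmin(floor((1 - u)^(-1 / 1.5)), max(3, floor(sqrt(n))))
      deg <- pmax(deg, 1) * spec@edgesPerNode
      if (sum(deg) %% 2 == 1) deg[1] <- deg[1] + 1
      g <- igraph::sample_degseq(deg, method = "configuration")
      g <- igraph::simplify(g)
    } else { # planted
      m <- round(n * spec@edgesPerNode / 2)
      g <- igraph::sample_gnm(n, m)
      sizes <- rep_len(spec@plantedCliqueSizes, spec@nPlantedCliques)
      deInNet <- which(nodes %in% c(lay$deUp, lay$deDown))
      pool <- c(.safeSample(deInNet),
                .safeSample(setdiff(seq_len(n), deInNet)))
      at <- 0
      for (s in sizes) {
        memb <- pool[at + seq_len(s)]; at <- at + s
        plantedCliques[[length(plantedCliques) + 1L]] <-
          sort(nodes[memb])
        pairs <- combn(memb, 2)
        g <- igraph::add_edges(g, as.vector(pairs))
      }
      if (spec@nPlantedHubs > 0) {
        hubIdx <- pool[at + seq_len(spec@nPlantedHubs)]
        plantedHubs <- sort(nodes[hubIdx])
        g <- igraph::simplify(g)
        # wire hubs up until they clear the empirical hub cutoff
        for (iter in seq_len(25)) {
          deg <- igraph::degree(g)
          cut <- mean(deg) + 2 * stats::sd(deg)
          short <- hubIdx[deg[hubIdx] < cut]
          if (!length(short)) break
          for (h in short) {
            want <- ceiling(cut - deg[h]) + 1
            cand <- setdiff(seq_len(n),
                            c(h, as.integer(igraph::neighbors(g, h))))
            if (length(cand) < want) want <- length(cand)
            if (want > 0) {
              # disease-module structure: hubs interact preferentially
              # with differentially expressed proteins
              candDe <- intersect(cand, deInNet)
              nDe <- min(length(candDe), round(0.8 * want))
              picked <- if (nDe) .safeSample(candDe, nDe) else integer()
              pick <- c(picked,
                        .safeSample(setdiff(cand, picked), want - nDe))
              g <- igraph::add_edges(g, rbind(rep(h, want), pick))
            }
          }
        }
      }
      igraph::simplify(g)
    }
  })
  g <- igraph::simplify(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  inter <- Interactome(nodes[el[, 1]], nodes[el[, 2]],
                       source = "synthetic")
  truth <- new("GroundTruth", deGenesUp = lay$deUp,
               deGenesDown = lay$deDown,
               plantedCliques = plantedCliques,
               plantedHubGenes = plantedHubs)
  list(interactome = inter, truth = truth)
}

#' Generate a synthetic complex catalog
#'
#' Complex member sets are sampled from the interactome node set with
#' sizes uniform over `complexSizeRange`. When planted cliques are
#' supplied, the first complex is guaranteed to contain the first planted
#' clique.
#'
#' @param interactome an [Interactome-class].
#' @param spec a [SyntheticSpec-class].
#' @param truth optional [GroundTruth-class] with planted cliques.
#' @return a [ComplexCatalog-class].
#' @export
generateComplexCatalog <- function(interactome, spec, truth = NULL) {
  stopifnot(is(interactome, "Interactome"), is(spec, "SyntheticSpec"))
  nodes <- networkNodes(interactome)
  if (!length(nodes)) stop("interactome must be non-empty")
  lo <- spec@complexSizeRange[1]; hi <- spec@complexSizeRange[2]
  if (lo > length(nodes))
    stop("complexSizeRange minimum (", lo, ") exceeds the ",
         length(nodes), " available proteins")
  if (spec@nComplexes == 0)
    return(ComplexCatalog(character(), character(), list()))
  withSeed(spec@seed + 3L, {
    sizes <- sample(seq(lo, min(hi, length(nodes))), spec@nComplexes,
                    replace = TRUE)
    members <- lapply(sizes, function(s) sample(nodes, s))
  })
  if (!is.null(truth) && length(truth@plantedCliques)) {
    cl <- truth@plantedCliques[[1]]
    extra <- setdiff(members[[1]], cl)
    need <- max(0, max(lo, length(cl)) - length(cl))
    members[[1]] <- unique(c(cl, extra))[seq_len(max(length(cl) + need,
                                                     length(cl)))]
    members[[1]] <- members[[1]][!is.na(members[[1]])]
  }
  ComplexCatalog(id = sprintf("CPX%04d", seq_len(spec@nComplexes)),
                 name = sprintf("synthetic complex %d",
                                seq_len(spec@nComplexes)),
                 members = members)
}

#' Generate a synthetic term annotation
#'
#' Half of the terms (rounded up) are enriched for planted DE genes: 80%
#' of their members are drawn from the DE set, the rest from the
#' background, so the over-representation filter has signal to detect.
#' The remaining terms are uniform random gene sets.
#'
#' @param genes character vector: the gene universe to annotate.
#' @param spec a [SyntheticSpec-class].
#' @param truth a [GroundTruth-class] with DE gene sets.
#' @return a [TermAnnotation-class] in namespace `"BP"`.
#' @export
generateTermAnnotation <- function(genes, spec, truth) {
  stopifnot(is(spec, "SyntheticSpec"), is(truth, "GroundTruth"))
  if (!length(genes)) stop("gene universe must be non-empty")
  if (spec@nTerms == 0)
    return(TermAnnotation(character(), character(), genes = list()))
  de <- intersect(c(truth@deGenesUp, truth@deGenesDown), genes)
  other <- setdiff(genes, de)
  nEnriched <- if (length(de)) ceiling(spec@nTerms / 2) else 0
  withSeed(spec@seed + 4L, {
    sets <- lapply(seq_len(spec@nTerms), function(i) {
      size <- sample(10:min(50, length(genes)), 1)
      if (i <= nEnriched) {
        nDe <- min(length(de), max(1, round(0.8 * size)))
        unique(c(sample(de, nDe),
                 sample(other, min(length(other), size - nDe))))
      } else {
        sample(genes, size)
      }
    })
  })
  TermAnnotation(id = sprintf("T%04d", seq_len(spec@nTerms)),
                 name = sprintf("synthetic process %d",
                                seq_len(spec@nTerms)),
                 namespace = "BP", genes = sets)
}

#' Generate a gene pair with planted group-wise correlations
#'
#' Returns a 2 x (nControl + nDisease) log2 matrix whose two rows have
#' population Pearson correlation `rControl` within the control samples
#' and `rDisease` within the disease samples, for testing co-expression
#' change recovery.
#'
#' @param rControl,rDisease target correlations in \[-1, 1\].
#' @param nControl,nDisease samples per group (>= 3).
#' @param seed integer seed.
#' @return list with `dataset` (an [ExpressionDataset-class] with genes
#'   `"PAIR1"`, `"PAIR2"`) and `change` (the planted rControl - rDisease).
#' @export
generateCoexpressionPair <- function(rControl, rDisease,
                                     nControl = 15, nDisease = 24,
                                     seed = 1) {
  stopifnot(abs(rControl) <= 1, abs(rDisease) <= 1,
            nControl >= 3, nDisease >= 3)
  gen <- function(r, n) {
    z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
    rbind(z1, r * z1 + sqrt(1 - r^2) * z2)
  }
  withSeed(seed, {
    m <- cbind(gen(rControl, nControl), gen(rDisease, nDisease))
  })
  dimnames(m) <- list(c("PAIR1", "PAIR2"),
                      c(sprintf("C%02d", seq_len(nControl)),
                        sprintf("D%02d", seq_len(nDisease))))
  group <- rep(c("control", "disease"), c(nControl, nDisease))
  list(dataset = ExpressionDataset(m + 8, group),
       change = rControl - rDisease)
}

#' Write a complete synthetic input bundle to disk
#'
#' Generates the expression matrix, phenotype table, interactome SIF,
#' complex catalog, GMT annotation, a known-disease-gene list (a seeded
#' half of the planted DE genes, emulating prior-literature curation),
#' a small neurotransmitter association table over a few planted DE
#' genes, and a ground-truth JSON sidecar. With `probesPerGene > 1` the
#' expression matrix is written with that many identical probe rows per
#' gene symbol, exercising the probe-collapse policy on read.
#'
#' @param spec a [SyntheticSpec-class].
#' @param dir output directory (created if needed).
#' @return invisibly, a named list of the file paths written.
#' @export
writeSyntheticBundle <- function(spec, dir) {
  stopifnot(is(spec, "SyntheticSpec"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  expr <- generateExpression(spec)
  inter <- generateInteractome(spec)
  catalog <- generateComplexCatalog(inter$interactome, spec,
                                    truth = inter$truth)
  annot <- generateTermAnnotation(rownames(expr$dataset), spec,
                                  expr$truth)
  de <- c(expr$truth@deGenesUp, expr$truth@deGenesDown)
  withSeed(spec@seed + 5L, {
    known <- sort(sample(de, floor(length(de) / 2)))
    neuroGenes <- if (length(de) >= 3) sort(sample(de, 3)) else de
  })
  paths <- list(
    expression = file.path(dir, "expression.tsv"),
    phenotype = file.path(dir, "phenotype.tsv"),
    interactome = file.path(dir, "interactome.sif"),
    complexes = file.path(dir, "complexes.tsv"),
    annotation = file.path(dir, "annotation.gmt"),
    known = file.path(dir, "known_genes.txt"),
    neuro = file.path(dir, "neurotransmitters.tsv"),
    truth = file.path(dir, "ground_truth.json"))
  m <- exprsValues(expr$dataset)
  if (spec@probesPerGene > 1) {
    idx <- rep(seq_len(nrow(m)), each = spec@probesPerGene)
    mProbes <- m[idx, , drop = FALSE]
    rownames(mProbes) <- rownames(m)[idx]
    .writeMatrixTsv(mProbes, paths$expression)
  } else {
    .writeMatrixTsv(m, paths$expression)
  }
  writePhenotype(sampleGroups(expr$dataset), paths$phenotype)
  writeSif(inter$interactome, paths$interactome)
  writeComplexCatalog(catalog, paths$complexes)
  writeGmt(annot, paths$annotation)
  writeLines(known, paths$known)
  neuro <- data.frame(gene = neuroGenes,
                      dopaminergic = "+", cholinergic = "-",
                      serotonergic = "-", adrenergic = "-",
                      glutamatergic = "-", GABAergic = "-",
                      stringsAsFactors = FALSE)
  write.table(neuro, paths$neuro, sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(
    list(deGenesUp = expr$truth@deGenesUp,
         deGenesDown = expr$truth@deGenesDown,
         plantedCliques = inter$truth@plantedCliques,
         plantedHubGenes = inter$truth@plantedHubGenes,
         knownGenes = known),
    paths$truth, pretty = TRUE)
  invisible(paths)
}
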