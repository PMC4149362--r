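test_that("generators are deterministic in the spec seed", {
  spec <- syntheticSpec(nGenes = 120, nProteins = 60, nComplexes = 5,
                        nTerms = 8, interactomeModel = "planted",
                        nPlantedCliques = 2, seed = 11)
  e1 <- generateExpression(spec); e2 <- generateExpression(spec)
  expect_identical(exprsValues(e1$dataset), exprsValues(e2$dataset))
  i1 <- generateInteractome(spec); i2 <- generateInteractome(spec)
  expect_identical(networkEdges(i1$interactome),
                   networkEdges(i2$interactome))
  expect_identical(i1$truth@plantedCliques, i2$truth@plantedCliques)
  c1 <- generateComplexCatalog(i1$interactome, spec, i1$truth)
  c2 <- generateComplexCatalog(i2$interactome, spec, i2$truth)
  expect_identical(geneSets(c1), geneSets(c2))
  a1 <- generateTermAnnotation(rownames(e1$dataset), spec, e1$truth)
  a2 <- generateTermAnnotation(rownames(e2$dataset), spec, e2$truth)
  expect_identical(geneSets(a1), geneSets(a2))
  # a different seed changes the data
  spec2 <- syntheticSpec(nGenes = 120, nProteins = 60, nComplexes = 5,
                         nTerms = 8, interactomeModel = "planted",
                         nPlantedCliques = 2, seed = 12)
  expect_false(identical(exprsValues(e1$dataset),
                         exprsValues(generateExpression(spec2)$dataset)))
})

test_that("null model plants nothing and group structure is honoured", {
  spec <- syntheticSpec(nGenes = 50, deFraction = 0, seed = 5)
  sim <- generateExpression(spec)
  expect_length(sim$truth@deGenesUp, 0)
  expect_length(sim$truth@deGenesDown, 0)
  expect_identical(dim(exprsValues(sim$dataset)), c(50L, 15L + 24L))
  expect_identical(as.integer(table(sampleGroups(sim$dataset))[
    c("control", "disease")]), c(15L, 24L))
})

test_that("planted DE genes shift the disease group by the effect size", {
  spec <- syntheticSpec(nGenes = 400, deFraction = 0.25, upFraction = 0.5,
                        effectSize = 2, noiseSd = 0.5, seed = 9)
  sim <- generateExpression(spec)
  m <- exprsValues(sim$dataset)
  grp <- sampleGroups(sim$dataset)
  diff <- rowMeans(m[, grp == "disease"]) - rowMeans(m[, grp == "control"])
  expect_gt(min(diff[sim$truth@deGenesUp]), 1)
  expect_lt(max(diff[sim$truth@deGenesDown]), -1)
  nonDe <- setdiff(rownames(m), c(sim$truth@deGenesUp,
                                  sim$truth@deGenesDown))
  expect_lt(max(abs(diff[nonDe])), 1)
})

test_that("invalid spec parameters raise errors naming the field", {
  expect_error(syntheticSpec(nControl = 2), "nControl")
  expect_error(syntheticSpec(deFraction = 1.5), "deFraction")
  expect_error(syntheticSpec(noiseSd = 0), "noiseSd")
  expect_error(syntheticSpec(interactomeModel = "smallworld"),
               "interactomeModel")
  expect_error(syntheticSpec(complexSizeRange = c(5, 2)),
               "complexSizeRange")
  # planted cliques cannot outnumber the proteins
  expect_error(syntheticSpec(nProteins = 10, nPlantedCliques = 5,
                             plantedCliqueSizes = 4),
               "nPlantedCliques")
})

test_that("planted interactome contains its cliques and hub structure", {
  spec <- syntheticSpec(nGenes = 300, nProteins = 150,
                        interactomeModel = "planted",
                        nPlantedCliques = 1, plantedCliqueSizes = 4,
                        nPlantedHubs = 3, seed = 21)
  res <- generateInteractome(spec)
  cl <- res$truth@plantedCliques[[1]]
  expect_length(cl, 4)
  edges <- networkEdges(res$interactome)
  keys <- paste0(edges$node1, "|", edges$node2)
  pairs <- combn(sort(cl), 2)
  expect_true(all(paste0(pairs[1, ], "|", pairs[2, ]) %in% keys))
  # planted hubs clear the empirical degree cutoff
  deg <- table(c(edges$node1, edges$node2))
  cut <- round(mean(deg) + 2 * sd(deg))
  expect_true(all(deg[res$truth@plantedHubGenes] >= cut))
})

test_that("scale-free degree distributions are heavy tailed", {
  ratios <- vapply(1:10, function(s) {
    spec <- syntheticSpec(nGenes = 600, nProteins = 500, edgesPerNode = 2,
                          interactomeModel = "scale_free", seed = s)
    edges <- networkEdges(generateInteractome(spec)$interactome)
    deg <- table(c(edges$node1, edges$node2))
    max(deg) / median(deg)
  }, numeric(1))
  expect_true(all(ratios >= 10))
})

test_that("complex catalog respects sizes and covers a planted clique", {
  spec <- syntheticSpec(nGenes = 200, nProteins = 100,
                        interactomeModel = "planted",
                        nPlantedCliques = 1, plantedCliqueSizes = 4,
                        nComplexes = 8, complexSizeRange = c(4, 8),
                        seed = 13)
  res <- generateInteractome(spec)
  cat <- generateComplexCatalog(res$interactome, spec, res$truth)
  sizes <- lengths(geneSets(cat))
  expect_length(sizes, 8)
  expect_true(all(sizes >= 4 & sizes <= 8))
  cl <- res$truth@plantedCliques[[1]]
  expect_true(any(vapply(geneSets(cat), function(m) all(cl %in% m),
                         logical(1))))
  # empty catalog
  spec0 <- syntheticSpec(nComplexes = 0, seed = 1)
  expect_identical(nrow(termInfo(generateComplexCatalog(
    res$interactome, spec0))), 0L)
  # infeasible size range
  specBad <- syntheticSpec(nGenes = 200, nProteins = 100,
                           complexSizeRange = c(500, 600), seed = 1)
  expect_error(generateComplexCatalog(res$interactome, specBad),
               "complexSizeRange")
})

test_that("enriched terms give the over-representation filter signal", {
  hits <- vapply(1:10, function(s) {
    spec <- syntheticSpec(nGenes = 400, deFraction = 0.1, nTerms = 10,
                          seed = s)
    sim <- generateExpression(spec)
    ann <- generateTermAnnotation(rownames(sim$dataset), spec, sim$truth)
    de <- c(sim$truth@deGenesUp, sim$truth@deGenesDown)
    rec <- overRepresentation(de, rownames(sim$dataset), ann)
    sel <- selectGenesInSignificantTerms(rec, ann, de, alpha = 0.05)
    mean(de %in% sel)
  }, numeric(1))
  expect_true(all(hits >= 0.8))
})

test_that("type-I error of the t stage is calibrated on null data", {
  alpha <- 0.001
  nGenes <- 2000
  frac <- vapply(1:20, function(s) {
    spec <- syntheticSpec(nGenes = nGenes, deFraction = 0, seed = 100 + s)
    sim <- generateExpression(spec)
    length(selectDeTtest(tTest(sim$dataset), alpha)) / nGenes
  }, numeric(1))
  bound <- 3 * sqrt(alpha * (1 - alpha) / (20 * nGenes))
  expect_lt(abs(mean(frac) - alpha), bound)
})

test_that("planted hubs are recovered by the topology classifier", {
  recovered <- vapply(1:10, function(s) {
    spec <- syntheticSpec(nGenes = 2000, nProteins = 500,
                          interactomeModel = "planted", seed = s)
    res <- generateInteractome(spec)
    net <- buildQQPPI(networkNodes(res$interactome), res$interactome)
    cls <- classifyNodes(net)
    all(res$truth@plantedHubGenes %in% hubs(cls))
  }, logical(1))
  expect_gte(sum(recovered), 9)
})

test_that("the written bundle round-trips through the readers", {
  spec <- syntheticSpec(nGenes = 80, nProteins = 40, nComplexes = 4,
                        nTerms = 5, probesPerGene = 2,
                        interactomeModel = "planted",
                        nPlantedCliques = 1, plantedCliqueSizes = 3,
                        seed = 31)
  dir <- withr::local_tempdir()
  paths <- writeSyntheticBundle(spec, dir)
  expect_true(all(file.exists(unlist(paths))))
  ds <- readExpression(paths$expression, paths$phenotype)
  sim <- generateExpression(spec)
  # probe rows are duplicates, so mean-collapse recovers the gene matrix
  expect_equal(exprsValues(ds), round(exprsValues(sim$dataset), 6),
               tolerance = 1e-9)
  inter <- readSif(paths$interactome)
  expect_identical(networkEdges(inter)[, c("node1", "node2")],
                   networkEdges(generateInteractome(spec)$interactome)[,
                     c("node1", "node2")])
})
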