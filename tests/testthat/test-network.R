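test_that("QQPPI induction keeps only query-query edges", {
  inter <- Interactome(c("A", "A", "C"), c("B", "C", "D"))
  net <- buildQQPPI(c("A", "B", "C"), inter)
  expect_setequal(networkNodes(net), c("A", "B", "C"))
  e <- networkEdges(net)
  expect_setequal(paste(e$node1, e$node2), c("A B", "A C"))
  # no intra-query edges: empty network by default
  empty <- buildQQPPI(c("X", "Y"), inter)
  expect_length(networkNodes(empty), 0)
  # keepIsolated retains edgeless queries
  iso <- buildQQPPI(c("A", "B", "Z"), inter, keepIsolated = TRUE)
  expect_true("Z" %in% networkNodes(iso))
})

test_that("induction equals a brute-force edge filter on random inputs", {
  for (s in 1:5) {
    set.seed(s)
    nodes <- sprintf("P%02d", 1:50)
    pairs <- combn(nodes, 2)
    keep <- runif(ncol(pairs)) < 0.08
    inter <- Interactome(pairs[1, keep], pairs[2, keep])
    query <- sample(nodes, 20)
    net <- buildQQPPI(query, inter)
    e <- networkEdges(inter)
    manual <- e[e$node1 %in% query & e$node2 %in% query, c("node1", "node2")]
    got <- networkEdges(net)[, c("node1", "node2")]
    expect_identical(paste(got$node1, got$node2),
                     paste(manual$node1, manual$node2))
    # monotone: growing the query grows the edge set
    bigger <- networkEdges(buildQQPPI(c(query, sample(setdiff(nodes, query),
                                                      10)), inter))
    expect_true(all(paste(got$node1, got$node2) %in%
                      paste(bigger$node1, bigger$node2)))
  }
})

test_that("merge is union with idempotence and provenance tracking", {
  a <- buildQQPPI(c("A", "B", "C"),
                  Interactome(c("A", "B"), c("B", "C"), source = "db1"))
  b <- buildQQPPI(c("A", "B", "D"),
                  Interactome(c("A", "A"), c("B", "D"), source = "db2"))
  m <- mergeNetworks(a, b)
  expect_setequal(networkNodes(m), c("A", "B", "C", "D"))
  e <- networkEdges(m)
  expect_identical(nrow(e), 3L)
  shared <- e$sources[e$node1 == "A" & e$node2 == "B"]
  expect_identical(shared, "db1;db2")
  # idempotence
  expect_identical(networkEdges(mergeNetworks(a, a))[, c("node1", "node2")],
                   networkEdges(a)[, c("node1", "node2")])
  # disjoint networks: edge counts add
  c1 <- buildQQPPI(c("X", "Y"), Interactome("X", "Y"))
  expect_identical(nrow(networkEdges(mergeNetworks(a, c1))),
                   nrow(networkEdges(a)) + 1L)
  # commutative at the edge-set level
  m2 <- mergeNetworks(b, a)
  expect_identical(networkEdges(m)[, c("node1", "node2")],
                   networkEdges(m2)[, c("node1", "node2")])
  # intersection keeps only shared edges
  mi <- mergeNetworks(a, b, mode = "intersection")
  expect_identical(paste(networkEdges(mi)$node1, networkEdges(mi)$node2),
                   "A B")
})

test_that("global statistics follow 2E/V and the table rounding", {
  k4 <- literalNet("A-B, A-C, A-D, B-C, B-D, C-D")
  s <- networkSummary(k4)
  expect_identical(c(s$nNodes, s$nEdges), c(4L, 6L))
  expect_equal(s$avgDegree, 3)
  expect_equal(s$maxDegree, 4 - 1)
  path3 <- literalNet("a-b, b-c")
  s3 <- networkSummary(path3)
  expect_equal(s3$avgDegree, 4 / 3)
  expect_equal(s3$avgDegreeRounded, 1.3)
  expect_warning(s0 <- networkSummary(buildQQPPI("Q", Interactome())),
                 "empty")
  expect_identical(s0$nNodes, 0)
})

test_that("printed node/edge counts reproduce the printed average degrees", {
  glob <- paperNetworkGlobal()
  avg <- round(2 * glob$edges / glob$nodes, 1)
  expect_equal(avg[glob$network == "ttest"], 3.4)
  expect_equal(avg[glob$network == "sam"], 2.8)
})
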