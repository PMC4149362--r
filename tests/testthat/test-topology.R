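test_that("betweenness matches closed forms on stars and paths", {
  star <- literalNet("H-L1, H-L2, H-L3, H-L4, H-L5")
  b <- betweennessOf(computeTopology(star))
  expect_equal(unname(b["H"]), 5 * 4 / 2)    # (n-1)(n-2)/2 with n = 6
  expect_true(all(b[paste0("L", 1:5)] == 0))
  path <- literalNet("a-b, b-c")
  expect_equal(unname(betweennessOf(computeTopology(path))["b"]), 1)
})

test_that("degree/betweenness match the brute-force oracle on random graphs", {
  for (s in 1:12) {
    net <- randomNet(n = sample(8:30, 1), p = runif(1, 0.1, 0.35),
                     seed = 400 + s)
    topo <- computeTopology(net)
    expect_equal(betweennessOf(topo), oracleBetweenness(net),
                 tolerance = 1e-9)
    expect_equal(sum(degreeOf(topo)), 2 * nrow(networkEdges(net)))
  }
})

test_that("tree betweenness equals the separated-pair count", {
  # in a tree every pair has a unique path, so betweenness(v) is the
  # number of pairs whose path passes through v
  for (s in 1:5) {
    set.seed(s)
    n <- sample(8:20, 1)
    nodes <- sprintf("T%02d", 1:n)
    parent <- vapply(2:n, function(i) sample(i - 1, 1), numeric(1))
    net <- buildQQPPI(nodes, Interactome(nodes[parent], nodes[2:n]))
    topo <- computeTopology(net)
    expect_equal(betweennessOf(topo), oracleBetweenness(net),
                 tolerance = 1e-9)
  }
})

test_that("hub cutoff arithmetic reproduces the published table rows", {
  moments <- paperDegreeMoments()
  co <- lapply(seq_len(nrow(moments)), function(i)
    hubCutoffFromMoments(moments$mean_degree[i], moments$sd_degree[i]))
  expect_equal(co[[which(moments$network == "ttest")]]@cutoff, 11.8)
  expect_equal(co[[which(moments$network == "ttest")]]@roundedCutoff, 12)
  expect_equal(co[[which(moments$network == "sam")]]@cutoff, 8.6)
  expect_equal(co[[which(moments$network == "sam")]]@roundedCutoff, 9)
})

test_that("hub classification selects degree >= M + 2S", {
  # star with 20 nodes: degrees are 19 and 1 x 19
  edges <- paste0("H-L", 1:19, collapse = ", ")
  star <- literalNet(edges)
  topo <- computeTopology(star)
  cut <- hubCutoff(topo)
  deg <- c(19, rep(1, 19))
  expect_equal(cut@meanDegree, mean(deg))
  expect_equal(cut@sdDegree, sd(deg))
  expect_identical(classifyHubs(topo, cut), "H")
  # regular graph: S = 0, cutoff degenerates to M, all nodes qualify
  square <- literalNet("A-B, B-C, C-D, A-D")
  topoSq <- computeTopology(square)
  expect_warning(cutSq <- hubCutoff(topoSq), "degenerate")
  expect_setequal(classifyHubs(topoSq, cutSq), c("A", "B", "C", "D"))
  # population vs sample SD
  cutPop <- suppressWarnings(hubCutoff(topoSq, sdMode = "population"))
  expect_equal(cutPop@sdDegree, 0)
  expect_error(hubCutoff(new("TopologyAttributes",
                             degree = c(A = 1), betweenness = c(A = 0))),
               "at least 2 nodes")
})

test_that("bottlenecks need top-half betweenness, low degree, two hubs", {
  # two star hubs joined only through a degree-2 bridge
  edges <- paste(c(paste0("H1-A", 1:6), paste0("H2-B", 1:6),
                   "H1-X", "H2-X"), collapse = ", ")
  net <- literalNet(edges)
  topo <- computeTopology(net)
  cut <- hubCutoff(topo)
  hubSet <- classifyHubs(topo, cut)
  expect_setequal(hubSet, c("H1", "H2"))
  bn <- classifyBottlenecks(net, topo, hubSet, cut)
  expect_identical(bn, "X")
  # hubs are never bottlenecks
  expect_length(intersect(bn, hubSet), 0)
  # with fewer than 2 hubs the bottleneck rule is unsatisfiable
  expect_length(classifyBottlenecks(net, topo, "H1", cut), 0)
})

test_that("classification is invariant to node relabeling order", {
  net1 <- literalNet("A-B, B-C, C-D, B-D, D-E")
  net2 <- literalNet("D-E, B-D, C-D, B-C, A-B")
  c1 <- classifyNodes(net1)
  c2 <- classifyNodes(net2)
  expect_identical(hubs(c1), hubs(c2))
  expect_identical(bottlenecks(c1), bottlenecks(c2))
  expect_identical(c1@evidence, c2@evidence)
})
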