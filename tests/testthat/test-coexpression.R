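test_that("change arithmetic reproduces published cells to 6 decimals", {
  tab <- paperComplexCoexpression()
  cells <- list(c("SF3A2", "SF3B1", 0.393901),
                c("MAP2K1", "MAPK1", 0.109098),
                c("CSNK2A1", "YWHAB", -0.419082),
                c("AMPH", "AP2A2", 0.183705))
  for (cell in cells) {
    row <- tab[tab$node1 == cell[1] & tab$node2 == cell[2], ][1, ]
    got <- coexpressionChange(row$r_control, row$r_disease)$change
    expect_equal(round(got, 6), as.numeric(cell[3]), tolerance = 1e-9)
  }
  # extreme case: perfectly correlated -> anti-correlated
  ext <- coexpressionChange(1, -1)
  expect_equal(ext$change, 2)
  expect_equal(ext$pctMaxChange, 100)
  # antisymmetry and linear percent scale
  expect_equal(coexpressionChange(0.3, 0.7)$change,
               -coexpressionChange(0.7, 0.3)$change)
  expect_equal(coexpressionChange(0.25, -0.25)$pctMaxChange, 25)
})

test_that("edge records use group-wise Pearson r", {
  ds <- toyDataset(seed = 10, nGenes = 4, nC = 5, nD = 6)
  m <- exprsValues(ds); grp <- sampleGroups(ds)
  edges <- data.frame(node1 = c("G1", "G1"), node2 = c("G2", "G3"))
  rec <- edgeCoexpression(edges, ds)
  expect_identical(nrow(rec), 2L)
  expect_equal(rec$rControl[1],
               cor(m["G1", grp == "control"], m["G2", grp == "control"]),
               tolerance = 1e-12)
  expect_equal(rec$rDisease[2],
               cor(m["G1", grp == "disease"], m["G3", grp == "disease"]),
               tolerance = 1e-12)
  expect_equal(rec$change, rec$rControl - rec$rDisease, tolerance = 1e-12)
})

test_that("identical rows correlate perfectly; affine maps keep |r| = 1", {
  m <- exprsValues(toyDataset(seed = 4, nGenes = 2, nC = 4, nD = 4))
  m <- rbind(m, DUP = m[1, ], AFF = 2.5 * m[1, ] + 3, NEG = -m[1, ])
  ds <- ExpressionDataset(m, rep(c("control", "disease"), each = 4))
  rec <- edgeCoexpression(data.frame(node1 = c("G1", "G1", "G1"),
                                     node2 = c("DUP", "AFF", "NEG")), ds)
  expect_equal(rec$rControl, c(1, 1, -1), tolerance = 1e-12)
  expect_equal(rec$rDisease, c(1, 1, -1), tolerance = 1e-12)
  expect_equal(rec$change, c(0, 0, 0), tolerance = 1e-12)
})

test_that("missing genes are skipped and constant vectors excluded", {
  m <- exprsValues(toyDataset(seed = 8, nGenes = 3, nC = 4, nD = 4))
  m <- rbind(m, FLAT = rep(7, 8))
  ds <- ExpressionDataset(m, rep(c("control", "disease"), each = 4))
  edges <- data.frame(node1 = c("G1", "G1", "ABSENT"),
                      node2 = c("G2", "FLAT", "G2"))
  expect_message(expect_warning(rec <- edgeCoexpression(edges, ds),
                                "constant"),
                 "ABSENT")
  expect_identical(nrow(rec), 1L)
  expect_identical(rec$node1, "G1")
  expect_identical(rec$node2, "G2")
})

test_that("a planted co-expression break is recovered", {
  planted <- 0.9 - 0.0      # correlated in control only
  err <- vapply(1:10, function(s) {
    sim <- generateCoexpressionPair(0.9, 0, seed = 600 + s)
    rec <- edgeCoexpression(data.frame(node1 = "PAIR1", node2 = "PAIR2"),
                            sim$dataset)
    rec$change - planted
  }, numeric(1))
  expect_lt(abs(mean(err)), 0.15)
})

test_that("complex co-expression groups records under their complex", {
  ds <- toyDataset(seed = 12, nGenes = 6, nC = 4, nD = 4)
  matches <- data.frame(id = c("10", "20"), name = c("ten", "twenty"),
                        nMembers = c(3, 2), nMatched = c(3, 2),
                        matched = c("G1;G2;G3", "G5;G6"),
                        stringsAsFactors = FALSE)
  netEdges <- data.frame(node1 = c("G1", "G2"), node2 = c("G2", "G3"))
  out <- complexCoexpression(matches, netEdges, ds)
  # complex 20 has no intra-complex network edge: zero rows
  expect_false("20" %in% out$complexId)
  expect_identical(out$complexId, rep("10", 2))
  expect_setequal(paste(out$node1, out$node2), c("G1 G2", "G2 G3"))
})
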