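test_that("group summaries match hand arithmetic and a two-pass oracle", {
  m <- rbind(G1 = c(1, 2, 3, 10, 11, 12, 13),
             G2 = rep(5, 7))
  colnames(m) <- sprintf("S%d", 1:7)
  ds <- ExpressionDataset(m, rep(c("control", "disease"), c(3, 4)))
  gs <- groupSummaries(ds)
  expect_equal(gs$meanControl[1], 2)
  expect_equal(gs$sdControl[1], 1)
  expect_equal(gs$meanDisease[2], 5)
  expect_equal(gs$sdDisease[2], 0)

  ds2 <- toyDataset(seed = 7, nGenes = 5, nC = 3, nD = 3)
  gs2 <- groupSummaries(ds2)
  m2 <- exprsValues(ds2); grp <- sampleGroups(ds2)
  for (i in 1:5) {
    o <- oracleMeanSd(m2[i, grp == "control"])
    expect_equal(gs2$meanControl[i], o$mean, tolerance = 1e-12)
    expect_equal(gs2$sdControl[i], o$sd, tolerance = 1e-12)
  }
  expect_error(groupSummaries(
    ExpressionDataset(m[, 1:4], c("control", rep("disease", 3)))),
    "2 samples per group")
})

test_that("welch t matches the closed form and stats::t.test", {
  m <- rbind(G1 = c(1, 2, 3, 4, 5, 6))
  colnames(m) <- sprintf("S%d", 1:6)
  ds <- ExpressionDataset(m, rep(c("control", "disease"), each = 3))
  rec <- tTest(ds, variant = "welch")
  ref <- t.test(c(1, 2, 3), c(4, 5, 6), var.equal = FALSE)
  expect_equal(rec$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(rec$df, unname(ref$parameter), tolerance = 1e-12)
  expect_equal(rec$p, ref$p.value, tolerance = 1e-12)
  # direct evaluation of the formula
  se <- sqrt(1 / 3 + 1 / 3)
  expect_equal(rec$t, (2 - 5) / se, tolerance = 1e-12)

  recP <- tTest(ds, variant = "pooled")
  refP <- t.test(c(1, 2, 3), c(4, 5, 6), var.equal = TRUE)
  expect_equal(recP$t, unname(refP$statistic), tolerance = 1e-12)
  expect_equal(recP$p, refP$p.value, tolerance = 1e-12)
})

test_that("t is antisymmetric in the groups and zero for equal means", {
  ds <- toyDataset(seed = 3, nGenes = 6, nC = 4, nD = 4)
  fwd <- tTest(ds)
  swapped <- ExpressionDataset(exprsValues(ds),
                               ifelse(sampleGroups(ds) == "control",
                                      "disease", "control"))
  bwd <- tTest(swapped)
  expect_equal(fwd$t, -bwd$t, tolerance = 1e-12)
  expect_equal(fwd$p, bwd$p, tolerance = 1e-12)

  m <- rbind(G1 = c(1, 3, 2, 2, 3, 1))
  colnames(m) <- sprintf("S%d", 1:6)
  dsEq <- ExpressionDataset(m, rep(c("control", "disease"), each = 3))
  rec <- tTest(dsEq)
  expect_equal(rec$t, 0)
  expect_equal(rec$p, 1)
})

test_that("welch equals pooled for equal variances and group sizes", {
  ds <- toyDataset(seed = 11, nGenes = 10, nC = 5, nD = 5)
  m <- exprsValues(ds)
  # force exactly equal sample variances by mirroring the control block
  m[, 6:10] <- m[, 1:5] + 1
  ds2 <- ExpressionDataset(m, sampleGroups(ds))
  w <- tTest(ds2, "welch"); p <- tTest(ds2, "pooled")
  expect_equal(w$t, p$t, tolerance = 1e-12)
  expect_equal(w$df, p$df, tolerance = 1e-12)
})

test_that("flat genes are flagged instead of silently zero", {
  m <- rbind(G1 = rep(4, 6), G2 = c(1, 1, 1, 2, 2, 2))
  colnames(m) <- sprintf("S%d", 1:6)
  ds <- ExpressionDataset(m, rep(c("control", "disease"), each = 3))
  rec <- tTest(ds)
  expect_false(rec$ok[1])          # same constant in both groups
  expect_true(rec$ok[2])           # distinct constants: infinite t
  expect_identical(rec$p[2], 0)
  expect_identical(selectDeTtest(rec, 0.001), "G2")
})

test_that("t selection respects the threshold and the null is calibrated", {
  ds <- toyDataset(seed = 5, nGenes = 20, nC = 5, nD = 5)
  rec <- tTest(ds)
  expect_identical(selectDeTtest(rec, 1), rec$gene[rec$p < 1])
  expect_length(selectDeTtest(rec, 1e-12), 0)
  sub <- selectDeTtest(rec, 0.05)
  expect_true(all(sub %in% selectDeTtest(rec, 0.5)))

  # null simulation: per-seed selected counts stay within Poisson(2)
  # 99% bounds (alpha * nGenes = 2 expected false positives)
  counts <- vapply(1:20, function(s) {
    spec <- syntheticSpec(nGenes = 2000, deFraction = 0, seed = 200 + s)
    sim <- generateExpression(spec)
    length(selectDeTtest(tTest(sim$dataset), 0.001))
  }, numeric(1))
  expect_true(all(counts <= qpois(0.995, 2)))
})
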