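test_that("hypergeometric tail matches an exhaustive sum", {
  background <- sprintf("B%02d", 1:20)
  term <- background[1:5]
  query <- c(background[1:4], background[20])   # k = 4 of K = 5, n = 5
  ann <- TermAnnotation("T1", "set", "BP", genes = list(term))
  rec <- overRepresentation(query, background, ann)
  expect_equal(rec$p, oracleHyperTail(4, 5, 20, 5), tolerance = 1e-12)
  expect_identical(c(rec$k, rec$K, rec$n, rec$N), c(4L, 5L, 5L, 20L))
})

test_that("degenerate overlaps give p = 1", {
  background <- sprintf("B%02d", 1:12)
  ann <- TermAnnotation(c("T1", "T2"), c("a", "b"), "BP",
                        genes = list(background[1:4], background))
  # disjoint query: P(X >= 0) = 1
  rec <- overRepresentation(background[5:8], background, ann)
  expect_equal(rec$p[rec$id == "T1"], 1)
  # query = background: k = K for every term, upper tail includes all mass
  recAll <- overRepresentation(background, background, ann)
  expect_equal(recAll$p, c(1, 1))
})

test_that("p is non-increasing in the overlap k", {
  N <- 40; K <- 10; n <- 8
  ps <- vapply(0:8, function(k) {
    if (k == 0) 1 else phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  }, numeric(1))
  background <- sprintf("B%02d", 1:N)
  ann <- TermAnnotation("T1", "t", "BP", genes = list(background[1:K]))
  got <- vapply(0:8, function(k) {
    query <- c(background[seq_len(k)],
               background[K + seq_len(n - k)])
    overRepresentation(query, background, ann)$p
  }, numeric(1))
  expect_equal(got, ps, tolerance = 1e-12)
  expect_true(all(diff(got) <= 1e-12))
})

test_that("query genes outside the background are rejected", {
  expect_error(overRepresentation(c("A", "Z"), c("A", "B"),
                                  TermAnnotation("T1", "t", "BP",
                                                 genes = list("A"))),
               "Z")
})

test_that("selection unions genes of significant terms only", {
  background <- sprintf("B%02d", 1:30)
  ann <- TermAnnotation(c("T1", "T2", "T3"), c("a", "b", "c"),
                        c("BP", "BP", "MF"),
                        genes = list(background[1:5], background[10:20],
                                     background[1:10]))
  query <- background[1:6]
  rec <- overRepresentation(query, background, ann)
  # alpha = 1 keeps every BP term: all query genes annotated in BP
  selAll <- selectGenesInSignificantTerms(rec, ann, query, alpha = 1,
                                          namespace = "BP")
  expect_identical(selAll, sort(intersect(query,
                                          union(background[1:5],
                                                background[10:20]))))
  # impossible alpha: nothing
  expect_length(selectGenesInSignificantTerms(rec, ann, query,
                                              alpha = 1e-12), 0)
  # T1 (5/5 in query's first five) is enriched; its genes are selected
  sel <- selectGenesInSignificantTerms(rec, ann, query, alpha = 0.05)
  expect_identical(sel, sort(intersect(query, background[1:5])))
  # namespace filter excludes the MF term even though it overlaps
  expect_false(any(background[7:10] %in% sel))
})

test_that("selection is invariant to term order", {
  background <- sprintf("B%02d", 1:25)
  g1 <- background[1:6]; g2 <- background[5:12]
  annA <- TermAnnotation(c("T1", "T2"), c("a", "b"), "BP",
                         genes = list(g1, g2))
  annB <- TermAnnotation(c("T2", "T1"), c("b", "a"), "BP",
                         genes = list(g2, g1))
  query <- background[1:8]
  sA <- selectGenesInSignificantTerms(
    overRepresentation(query, background, annA), annA, query, 0.25)
  sB <- selectGenesInSignificantTerms(
    overRepresentation(query, background, annB), annB, query, 0.25)
  expect_identical(sA, sB)
})
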