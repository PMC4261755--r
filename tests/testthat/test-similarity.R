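# hand-built pair: A has rows {a,b,c,d,e} and 4 edges; B shares rows
# {a,b,c,d} and 2 edges and is the larger graph on both counts
makeFractionPair <- function() {
  a <- parseBNGL(bnglText(
    "begin molecule types", " M1(a,b)", " M2(c,d)", " M3(e)",
    "end molecule types",
    "begin reaction rules",
    " M1(a) + M2(c) -> M1(a!1).M2(c!1) k",
    " M1(b) + M2(d) -> M1(b!1).M2(d!1) k",
    " M1(a) + M3(e) -> M1(a!1).M3(e!1) k",
    " M1(b) + M3(e) -> M1(b!1).M3(e!1) k",
    "end reaction rules"), name = "A")
  b <- parseBNGL(bnglText(
    "begin molecule types", " M1(a,b)", " M2(c,d)", " M4(f,g,h)",
    "end molecule types",
    "begin reaction rules",
    " M1(a) + M2(c) -> M1(a!1).M2(c!1) k",
    " M1(b) + M2(d) -> M1(b!1).M2(d!1) k",
    " M4(f) + M4(g) -> M4(f!1).M4(g!1) k",
    " M4(f) + M4(h) -> M4(f!1).M4(h!1) k",
    " M4(g) + M4(h) -> M4(g!1).M4(h!1) k",
    "end reaction rules"), name = "B")
  list(a = contactMap(a), b = contactMap(b))
}

test_that("matrix rows are states plus stateless components", {
  m <- parseBNGL(bnglText("begin molecule types", " A(x,y~U~P)",
                          "end molecule types"), name = "rows")
  expect_equal(matrixRows(contactMap(m)),
               c("A.x#1", "A.y#1~P", "A.y#1~U"))
  m2 <- parseBNGL(bnglText("begin molecule types", " B()",
                           "end molecule types"), name = "rows2")
  expect_equal(matrixRows(contactMap(m2)), "B.B#1")
})

test_that("the adjacency matrix encodes edges over rows, self-edges on the diagonal", {
  m <- suppressWarnings(parseBNGL(bnglText(
    "begin molecule types", " R(b~Y~pY)", " K(u)", "end molecule types",
    "begin reaction rules",
    " R(b~pY) + K(u) -> R(b~pY!1).K(u!1) k",
    " K(u) + K(u) -> K(u!1).K(u!1) k",
    "end reaction rules"), name = "adj"))
  A <- adjacencyMatrix(contactMap(m))
  expect_true(A["K.u#1", "R.b#1~pY"])
  expect_true(A["R.b#1~pY", "K.u#1"])
  expect_false(A["K.u#1", "R.b#1~Y"])  # qualified endpoint covers one state row
  expect_true(A["K.u#1", "K.u#1"])
  expect_true(isSymmetric(A))
})

test_that("shared counts follow identifier equality", {
  cm <- contactMap(toyBindModel())
  sc <- sharedCounts(cm, cm)
  expect_equal(unname(sc), c(length(matrixRows(cm)), length(edgeIds(cm))))
  other <- contactMap(parseBNGL(bnglText(
    "begin molecule types", " Z(q)", "end molecule types"), name = "z"))
  expect_equal(unname(sharedCounts(cm, other)), c(0L, 0L))
})

test_that("fractions use the smaller graph per measure; hand case gives 0.8 and 0.5", {
  p <- makeFractionPair()
  expect_equal(length(matrixRows(p$a)), 5L)
  expect_equal(length(edgeIds(p$a)), 4L)
  sc <- sharedCounts(p$a, p$b)
  expect_equal(unname(sc), c(4L, 2L))
  fr <- sharedFractions(p$a, p$b)
  expect_equal(unname(fr), c(0.8, 0.5))
  expect_equal(absoluteSimilarity(p$a, p$b), 4 * 0.8 + 2 * 0.5)
  # symmetry
  expect_equal(sharedFractions(p$b, p$a), fr)
})

test_that("a subgraph scores 100% on both fractions regardless of the supergraph size", {
  cms <- loadFixtureMaps("egfr_synthetic")
  fr <- sharedFractions(cms$egfr_core, cms$egfr)
  expect_equal(unname(fr), c(1, 1))
  expect_equal(absoluteSimilarity(cms$egfr_core, cms$egfr),
               length(matrixRows(cms$egfr_core)) + length(edgeIds(cms$egfr_core)))
})

test_that("zero-denominator pairs score zero instead of dividing by zero", {
  empty <- contactMap(parseBNGL("", name = "empty"))
  cm <- contactMap(toyBindModel())
  expect_equal(unname(sharedFractions(empty, cm)), c(0, 0))
  expect_equal(absoluteSimilarity(empty, cm), 0)
  # edgeless model: edge fraction is 0, node term unaffected
  edgeless <- contactMap(parseBNGL(bnglText(
    "begin molecule types", " A(x)", "end molecule types"), name = "el"))
  fr <- sharedFractions(edgeless, cm)
  expect_equal(unname(fr["edges"]), 0)
  expect_equal(unname(fr["nodes"]), 1)
})

test_that("unstructured attachments count as edges only when requested", {
  m <- parseBNGL(bnglText(
    "begin molecule types", " A(x)", "end molecule types",
    "begin reaction rules", " 0 -> A(x) ksyn", "end reaction rules"),
    name = "syn")
  cm <- contactMap(m)
  expect_equal(unname(sharedCounts(cm, cm)["edges"]), 0L)
  expect_equal(unname(sharedCounts(cm, cm, countUnstructured = TRUE)["edges"]), 1L)
})

test_that("similarity matrices equal pairwise recomputation, entrywise", {
  fam <- generateFamily(familySpec(nModels = 5L, seed = 99))
  cms <- lapply(names(fam$models), function(nm)
    suppressWarnings(contactMap(parseBNGL(text = fam$models[[nm]], name = nm))))
  sm <- similarityMatrices(cms)
  for (i in 1:5) for (j in 1:5) {
    sc <- sharedCounts(cms[[i]], cms[[j]])
    expect_equal(sm@sharedNodes[i, j], unname(sc["nodes"]))
    expect_equal(sm@sharedEdges[i, j], unname(sc["edges"]))
    expect_equal(sm@absolute[i, j], absoluteSimilarity(cms[[i]], cms[[j]]))
  }
  expect_identical(sm@absolute, t(sm@absolute))
  # diagonal self-score law
  for (i in 1:5)
    expect_equal(sm@absolute[i, i],
                 length(matrixRows(cms[[i]])) + length(edgeIds(cms[[i]])))
})

test_that("most complete model maximizes rows + edges, ties broken by name", {
  cms <- loadFixtureMaps("egfr_synthetic")
  sizes <- vapply(cms, function(cm)
    length(matrixRows(cm)) + length(edgeIds(cm)), 0)
  expect_equal(mostComplete(unname(cms)), unname(which.max(sizes)))
  # ties: identical copies sort by name
  cmA <- contactMap(toyBindModel("beta"))
  cmB <- contactMap(toyBindModel("alpha"))
  expect_equal(mostComplete(list(cmA, cmB)), 2L)
})

test_that("family ordering puts the reference first and sorts by score then name", {
  cms <- loadFixtureMaps("egfr_synthetic")
  h <- cms$egfr; g <- cms$egfr_core
  d <- contactMap(parseBNGL(bnglText(
    "begin molecule types", " Zed(q)", "end molecule types"), name = "zed"))
  fo <- sortFamily(list(h, g, d))
  expect_equal(fo@ordering, c(1L, 2L, 3L))  # H, then G (subgraph), then disjoint
  expect_equal(fo@scores[3L], 0)
  # permutation invariance
  fo2 <- sortFamily(list(d, g, h))
  expect_equal(fo@modelNames[fo@ordering], fo2@modelNames[fo2@ordering])
  # identical copies: name order after the reference
  copies <- list(contactMap(toyBindModel("c")), contactMap(toyBindModel("a")),
                 contactMap(toyBindModel("b")))
  fo3 <- sortFamily(copies)
  expect_equal(fo3@modelNames[fo3@ordering], c("a", "b", "c"))
})

test_that("similarity laws hold under randomized families", {
  for (s in 1:6) {
    fam <- generateFamily(familySpec(seed = 200 + s))
    cms <- lapply(names(fam$models), function(nm)
      suppressWarnings(contactMap(parseBNGL(text = fam$models[[nm]], name = nm))))
    for (i in seq_along(cms)) {
      # self-score law
      expect_equal(absoluteSimilarity(cms[[i]], cms[[i]]),
                   length(matrixRows(cms[[i]])) + length(edgeIds(cms[[i]])))
      for (j in seq_along(cms)) {
        expect_equal(sharedCounts(cms[[i]], cms[[j]]),
                     sharedCounts(cms[[j]], cms[[i]]))
        expect_equal(absoluteSimilarity(cms[[i]], cms[[j]]),
                     absoluteSimilarity(cms[[j]], cms[[i]]))
      }
    }
  }
})

test_that("growing both models with a shared element never lowers the score", {
  base <- c("begin molecule types", " M1(a,b)", " M2(c,d)",
            "end molecule types",
            "begin reaction rules",
            " M1(a) + M2(c) -> M1(a!1).M2(c!1) k")
  extra <- " M1(b) + M2(d) -> M1(b!1).M2(d!1) k"
  a1 <- contactMap(parseBNGL(bnglText(base, "end reaction rules"), name = "a"))
  p <- makeFractionPair()
  s0 <- absoluteSimilarity(a1, a1)
  a2 <- contactMap(parseBNGL(bnglText(base, extra, "end reaction rules"), name = "a"))
  expect_gte(absoluteSimilarity(a2, a2), s0)
  # adding an element to only the larger model cannot raise the node fraction
  frBefore <- sharedFractions(p$a, p$b)
  bigger <- parseBNGL(bnglText(
    "begin molecule types", " M1(a,b)", " M2(c,d)", " M4(f,g,h,i)",
    "end molecule types",
    "begin reaction rules",
    " M1(a) + M2(c) -> M1(a!1).M2(c!1) k",
    " M1(b) + M2(d) -> M1(b!1).M2(d!1) k",
    " M4(f) + M4(g) -> M4(f!1).M4(g!1) k",
    " M4(f) + M4(h) -> M4(f!1).M4(h!1) k",
    " M4(g) + M4(h) -> M4(g!1).M4(h!1) k",
    "end reaction rules"), name = "B")
  frAfter <- sharedFractions(p$a, contactMap(bigger))
  expect_lte(unname(frAfter["nodes"]), unname(frBefore["nodes"]))
})
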