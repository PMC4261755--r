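test_that("a homodimerization rule yields one molecule node and one self-edge", {
  m <- parseBNGL(bnglText("begin reaction rules",
                          " A(x) + A(x) -> A(x!1).A(x!1) kp",
                          "end reaction rules"), name = "homo")
  cm <- contactMap(m)
  s <- cmapStats(cm)
  expect_equal(unname(s["nMolecules"]), 1L)
  expect_equal(unname(s["nEdges"]), 1L)
  expect_equal(edgeIds(cm), "{A.x#1|A.x#1}")
})

test_that("a pure state-change rule marks the component modifiable with no edges", {
  m <- suppressWarnings(parseBNGL(bnglText(
    "begin molecule types", " A(y~U~P)", "end molecule types",
    "begin reaction rules", " A(y~U) -> A(y~P) k", "end reaction rules"),
    name = "mod"))
  cm <- contactMap(m)
  s <- cmapStats(cm)
  expect_equal(unname(s["nModifiable"]), 1L)
  expect_equal(unname(s["nEdges"]), 0L)
})

test_that("molecules with no components get the implicit whole-molecule component", {
  m <- parseBNGL(bnglText("begin molecule types", " B()", "end molecule types"),
                 name = "imp")
  cm <- contactMap(m)
  expect_setequal(elementIds(cm), c("B", "B.B#1"))
})

test_that("state-qualified and unqualified endpoints give distinct edges", {
  m <- suppressWarnings(parseBNGL(bnglText(
    "begin molecule types", " R(b~Y~pY)", " K(u,s)", "end molecule types",
    "begin reaction rules",
    " R(b~Y) + K(u) -> R(b~Y!1).K(u!1) k",
    " R(b~pY) + K(s) -> R(b~pY!1).K(s!1) k",
    " R(b) + K(u) -> R(b!1).K(u!1) k",
    "end reaction rules"), name = "qual"))
  cm <- contactMap(m)
  expect_setequal(edgeIds(cm), c("{K.u#1|R.b#1~Y}", "{K.s#1|R.b#1~pY}",
                                 "{K.u#1|R.b#1}"))
})

test_that("wildcard bonds set binds but contribute no edge, with a warning", {
  expect_warning(cm <- contactMap(parseBNGL(bnglText(
    "begin molecule types", " A(x)", "end molecule types",
    "begin reaction rules", " A(x!+) -> A(x) k", "end reaction rules"),
    name = "wild")), "wildcard")
  expect_equal(nrow(cm@edges), 0L)
  expect_true(cm@molecules[[1L]]$components[[1L]]$binds)
})

test_that("synthesis and degradation rules create unstructured nodes", {
  m <- parseBNGL(bnglText(
    "begin molecule types", " egf(r)", " egfr(l)", "end molecule types",
    "begin reaction rules",
    " 0 -> egf(r) ksyn",
    " egfr(l) -> 0 kdeg",
    "end reaction rules"), name = "sd")
  cm <- contactMap(m)
  expect_setequal(cm@unstructured$id, c("egf.@syn", "egfr.@deg"))
  # synthesis of a molecule with a written state must not mark it modifiable
  m2 <- suppressWarnings(parseBNGL(bnglText(
    "begin molecule types", " A(y~U~P)", "end molecule types",
    "begin reaction rules", " 0 -> A(y~U) ksyn", "end reaction rules"),
    name = "sd2"))
  expect_equal(unname(cmapStats(contactMap(m2))["nModifiable"]), 0L)
})

test_that("element ids are idempotent and match the generator's bookkeeping", {
  for (s in 1:8) {
    fam <- generateFamily(familySpec(seed = s))
    for (nm in names(fam$models)) {
      m <- parseBNGL(text = fam$models[[nm]], name = nm)
      cm1 <- suppressWarnings(contactMap(m))
      cm2 <- suppressWarnings(contactMap(m))
      expect_identical(elementIds(cm1), elementIds(cm2))
      expect_identical(elementIds(cm1), fam$truth$elements[[nm]])
      expect_identical(length(elementIds(cm1)),
                       sum(cmapStats(cm1)[c("nMolecules", "nComponents",
                                            "nStates", "nUnstructured",
                                            "nEdges")]))
    }
  }
})

test_that("duplicating a rule changes contributing rules but no element", {
  base <- c("begin molecule types", " A(x)", " B(y)", "end molecule types",
            "begin reaction rules",
            " A(x) + B(y) -> A(x!1).B(y!1) k1")
  m1 <- parseBNGL(bnglText(base, "end reaction rules"), name = "one")
  m2 <- parseBNGL(bnglText(base, " A(x) + B(y) -> A(x!1).B(y!1) k2",
                           "end reaction rules"), name = "one")
  cm1 <- contactMap(m1); cm2 <- contactMap(m2)
  expect_identical(elementIds(cm1), elementIds(cm2))
  expect_length(cm2@edges$rules[[1L]], 2L)
})

test_that("deleting a rule never adds elements (subgraph construction)", {
  for (s in 1:5) {
    fam <- generateFamily(familySpec(seed = s, nModels = 1L))
    m <- parseBNGL(text = fam$models[[1L]], name = "m")
    full <- suppressWarnings(elementIds(contactMap(m)))
    for (k in seq_along(m@rules)) {
      reduced <- m
      reduced@rules <- m@rules[-k]
      expect_length(setdiff(suppressWarnings(elementIds(contactMap(reduced))),
                            full), 0L)
    }
  }
})

test_that("fixture family stats match their planted structure", {
  cms <- loadFixtureMaps("fceri_synthetic")
  tri <- cmapStats(cms$fceri_fyn_trimer)
  fyn <- cmapStats(cms$fceri_fyn)
  # the trimer differs from the fyn model by one extra ligand site only
  expect_equal(unname(tri["nComponents"] - fyn["nComponents"]), 1L)
  expect_equal(unname(tri["nEdges"]), unname(fyn["nEdges"]))
  expect_equal(unname(tri["nMatrixRows"] - fyn["nMatrixRows"]), 1L)
})
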