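test_that("identical maps share everything; disjoint maps share nothing", {
  cm <- contactMap(toyBindModel())
  res <- compareSimilarities(cm, cm)
  expect_identical(res@shared, elementIds(cm))
  d <- compareDifferences(cm, cm)
  expect_length(d@onlyA, 0L)
  expect_length(d@onlyB, 0L)
  other <- contactMap(parseBNGL(bnglText(
    "begin molecule types", " Zed(q)", "end molecule types"), name = "z"))
  expect_length(compareSimilarities(cm, other)@shared, 0L)
})

test_that("the trimer variant differs from the fyn model by the third ligand site", {
  cms <- loadFixtureMaps("fceri_synthetic")
  d <- compareDifferences(cms$fceri_fyn_trimer, cms$fceri_fyn)
  expect_identical(d@onlyA, "Lig.l#3")
  expect_length(d@onlyB, 0L)  # fyn model is a complete subgraph: empty overlay
  s <- compareSimilarities(cms$fceri_fyn, cms$fceri_fyn_trimer)
  # the shared set covers the whole common core
  expect_identical(s@shared, elementIds(cms$fceri_fyn))
  expect_true(all(c("Rec", "Syk", "Lyn", "Lig", "Rec.a#1", "Syk.tSH2#1",
                    "Lyn.U#1", "Lig.l#1", "Lig.l#2") %in% s@shared))
})

test_that("shared and only sets partition each model's elements", {
  for (s in 1:6) {
    fam <- generateFamily(familySpec(seed = 300 + s))
    cms <- lapply(names(fam$models), function(nm)
      suppressWarnings(contactMap(parseBNGL(text = fam$models[[nm]], name = nm))))
    for (i in seq_along(cms)) for (j in seq_along(cms)) {
      sh <- compareSimilarities(cms[[i]], cms[[j]])@shared
      d <- compareDifferences(cms[[i]], cms[[j]])
      expect_identical(sort(c(sh, d@onlyA)), elementIds(cms[[i]]))
      expect_identical(sort(c(sh, d@onlyB)), elementIds(cms[[j]]))
      expect_length(intersect(d@onlyA, elementIds(cms[[j]])), 0L)
      # consistency with the metric's shared counts: the metric's "nodes"
      # are elements that are adjacency rows in both models
      sc <- sharedCounts(cms[[i]], cms[[j]])
      bothRows <- intersect(matrixRows(cms[[i]]), matrixRows(cms[[j]]))
      expect_length(intersect(sh, bothRows), sc[["nodes"]])
      expect_length(intersect(sh, edgeIds(cms[[i]])), sc[["edges"]])
    }
  }
})

test_that("results equal brute-force pairwise enumeration on small maps", {
  small <- list(
    contactMap(toyBindModel()),
    contactMap(parseBNGL(bnglText(
      "begin molecule types", " A(x,y~U~P)", " B(y)", "end molecule types",
      "begin reaction rules", " A(x) + B(y) -> A(x!1).B(y!1) k",
      "end reaction rules"), name = "small2")),
    contactMap(parseBNGL(bnglText(
      "begin molecule types", " B(y)", " C(z)", "end molecule types",
      "begin reaction rules", " B(y) + C(z) -> B(y!1).C(z!1) k",
      "end reaction rules"), name = "small3")),
    contactMap(parseBNGL("", name = "empty")))
  for (a in small) for (b in small) {
    expect_lte(length(elementIds(a)), 12L)
    expect_identical(compareSimilarities(a, b)@shared, bruteSharedElements(a, b))
    d <- compareDifferences(a, b)
    expect_identical(d@onlyA, bruteOnly(a, b))
    expect_identical(d@onlyB, bruteOnly(b, a))
  }
})

test_that("findElement reports membership across the family", {
  cms <- unname(loadFixtureMaps("fceri_synthetic"))
  res <- findElement(cms, "Rec.a#1")
  expect_true(all(res@membership))  # core element present everywhere
  res2 <- findElement(cms, "Lig.l#3")
  expect_equal(sum(res2@membership), 2L)  # the two trimer variants
  res3 <- findElement(cms, "Fabricated")
  expect_false(any(res3@membership))
  expect_error(findElement(cms, "not an id!"), "malformed element id")
  # exhaustive self-membership for one model
  k <- 1L
  for (id in elementIds(cms[[k]]))
    expect_true(findElement(cms, id)@membership[[k]])
})
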