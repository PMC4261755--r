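test_that("a single unpinned molecule sits at the origin", {
  cm <- contactMap(parseBNGL(bnglText(
    "begin molecule types", " A(x)", "end molecule types"), name = "one"))
  lay <- forceLayout(cm, seed = 1)
  mol <- lay@nodes[lay@nodes$kind == "molecule", ]
  expect_equal(c(mol$x, mol$y), c(0, 0))
})

test_that("pinned coordinates pass through bit-identically", {
  cm <- contactMap(toyBindModel())
  pin <- storedLayout(c("A", "B"), c(123.456789, -20.25), c(-7.125, 301.5))
  lay <- forceLayout(cm, seed = 5, pinned = pin)
  mols <- lay@nodes[lay@nodes$kind == "molecule", ]
  expect_identical(mols$x[match(c("A", "B"), mols$id)], c(123.456789, -20.25))
  expect_identical(mols$y[match(c("A", "B"), mols$id)], c(-7.125, 301.5))
  expect_true(all(mols$pinned))
  # pinned components too
  pin2 <- storedLayout(c("A", "B", "A.x#1"), c(0, 100, 3.5), c(0, 0, -2.25))
  lay2 <- forceLayout(cm, seed = 5, pinned = pin2)
  comp <- lay2@nodes[lay2@nodes$id == "A.x#1", ]
  expect_identical(c(comp$x, comp$y), c(3.5, -2.25))
})

test_that("layouts are deterministic in the seed and differ only off-pin across seeds", {
  cms <- loadFixtureMaps("egfr_synthetic")
  cm <- cms$egfr
  l1 <- forceLayout(cm, seed = 42)
  l2 <- forceLayout(cm, seed = 42)
  expect_identical(l1@nodes, l2@nodes)
  l3 <- forceLayout(cm, seed = 43)
  expect_false(identical(l1@nodes, l3@nodes))
  pin <- storedLayout("egfr", 50, 60)
  p1 <- forceLayout(cm, seed = 1, pinned = pin)
  p2 <- forceLayout(cm, seed = 2, pinned = pin)
  g1 <- p1@nodes[p1@nodes$id == "egfr", ]
  g2 <- p2@nodes[p2@nodes$id == "egfr", ]
  expect_identical(c(g1$x, g1$y), c(50, 60))
  expect_identical(c(g2$x, g2$y), c(50, 60))
})

test_that("unpinned components lie inside their molecule's box", {
  for (s in 1:5) {
    fam <- generateFamily(familySpec(seed = 400 + s))
    for (nm in names(fam$models)) {
      cm <- suppressWarnings(contactMap(parseBNGL(text = fam$models[[nm]], name = nm)))
      lay <- forceLayout(cm, seed = s)
      nd <- lay@nodes
      mols <- nd[nd$kind == "molecule", ]
      comps <- nd[nd$kind == "component", ]
      for (k in seq_len(nrow(comps))) {
        box <- mols[mols$id == comps$molecule[k], ]
        expect_true(comps$x[k] - comps$w[k] / 2 >= box$x - box$w / 2 - 1e-9)
        expect_true(comps$x[k] + comps$w[k] / 2 <= box$x + box$w / 2 + 1e-9)
        expect_true(comps$y[k] - comps$h[k] / 2 >= box$y - box$h / 2 - 1e-9)
        expect_true(comps$y[k] + comps$h[k] / 2 <= box$y + box$h / 2 + 1e-9)
      }
    }
  }
})

test_that("unknown pinned identifiers warn and are ignored", {
  cm <- contactMap(toyBindModel())
  expect_warning(forceLayout(cm, seed = 1,
                             pinned = storedLayout("Nope", 1, 2)),
                 "not in the contact map")
})

test_that("stabilization pins shared elements to identical positions in every panel", {
  cms <- unname(loadFixtureMaps("fceri_synthetic"))
  ref <- asStoredLayout(forceLayout(cms[[mostComplete(cms)]], seed = 9))
  lays <- suppressWarnings(stabilizeLayouts(cms, ref, seed = 9))
  refIds <- positions(ref)$id
  for (i in seq_along(cms)) for (j in seq_along(cms)) {
    ni <- lays[[i]]@nodes; nj <- lays[[j]]@nodes
    shared <- intersect(intersect(ni$id, nj$id), refIds)
    ki <- match(shared, ni$id); kj <- match(shared, nj$id)
    expect_identical(ni$x[ki], nj$x[kj])
    expect_identical(ni$y[ki], nj$y[kj])
  }
})

test_that("a reference covering a subgraph pins all of its molecules and components", {
  cms <- loadFixtureMaps("egfr_synthetic")
  ref <- asStoredLayout(forceLayout(cms$egfr, seed = 3))
  lays <- suppressWarnings(stabilizeLayouts(list(cms$egfr_core), ref, seed = 3))
  nd <- lays[[1L]]@nodes
  expect_true(all(nd$pinned[nd$kind %in% c("molecule", "component")]))
  # identical models stabilize to identical layouts
  lays2 <- suppressWarnings(stabilizeLayouts(list(cms$egfr, cms$egfr), ref, seed = 3))
  expect_identical(lays2[[1L]]@nodes, lays2[[2L]]@nodes)
})
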