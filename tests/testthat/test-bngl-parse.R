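test_that("a reversible binding rule parses into one rule with a shared bond tag", {
  m <- parseBNGL(bnglText(
    "begin reaction rules",
    " egf(r) + egfr(l) <-> egf(r!1).egfr(l!1) kp1, km1",
    "end reaction rules"), name = "lig")
  expect_length(rules(m), 1L)
  r <- rules(m)[[1L]]
  expect_true(r$reversible)
  expect_equal(r$rates, c("kp1", "km1"))
  expect_length(r$reactants, 2L)  # two separate complexes
  expect_length(r$products, 1L)   # one bound complex
  prod <- r$products[[1L]]
  expect_equal(vapply(prod, `[[`, "", "name"), c("egf", "egfr"))
  expect_equal(prod[[1L]]$components[[1L]]$bond, "1")
  expect_equal(prod[[2L]]$components[[1L]]$bond, "1")
})

test_that("empty blocks and block structure are tolerated", {
  m <- parseBNGL(bnglText(
    "begin model",
    "begin parameters", " k 1", "end parameters",
    "begin reaction rules", "end reaction rules",
    "end model",
    "generate_network({overwrite=>1})",
    "simulate({method=>\"ode\",t_end=>10})"), name = "empty")
  expect_length(rules(m), 0L)
  expect_length(moleculeTypes(m), 0L)
})

test_that("comments, continuations, labels and leading indices are handled", {
  m <- parseBNGL(bnglText(
    "begin molecule types",
    " A(x,y~U~P)  # receptor-like",
    "end molecule types",
    "begin reaction rules",
    " bindAB: A(x) + \\",
    "   A(x) -> A(x!1).A(x!1) kon",
    " 2 A(y~U) -> A(y~P) kcat",
    "end reaction rules"), name = "cont")
  expect_length(rules(m), 2L)
  expect_equal(rules(m)[[1L]]$label, "bindAB")
  expect_false(rules(m)[[2L]]$reversible)
  expect_equal(rules(m)[[2L]]$rates, "kcat")
})

test_that("malformed bond tags are rejected with the rule and tag named", {
  bad1 <- bnglText("begin reaction rules",
                   " A(x) -> A(x!1) k", "end reaction rules")
  expect_error(parseBNGL(bad1, name = "bad"), "!1.*appear exactly twice|bond tag")
  bad3 <- bnglText("begin reaction rules",
                   " A(x!2).A(x!2).A(y!2) -> A(x) k", "end reaction rules")
  expect_error(parseBNGL(bad3, name = "bad"), "!2")
})

test_that("unknown blocks warn and are skipped; undeclared states are appended", {
  expect_warning(
    m <- parseBNGL(bnglText(
      "begin compartments", " PM 2 1", "end compartments",
      "begin reaction rules", " A(x) + A(x) -> A(x!1).A(x!1) k",
      "end reaction rules"), name = "w"),
    "unknown block")
  expect_length(rules(m), 1L)

  expect_warning(
    m2 <- parseBNGL(bnglText(
      "begin molecule types", " A(y~U)", "end molecule types",
      "begin reaction rules", " A(y~U) -> A(y~P) k", "end reaction rules"),
      name = "st"),
    "not declared")
  states <- moleculeTypes(m2)[[1L]]$components[[1L]]$states
  expect_setequal(states, c("U", "P"))
})

test_that("molecules absent from the declarations are auto-declared from usage", {
  m <- parseBNGL(bnglText(
    "begin reaction rules",
    " Lig(l,l) + Rec(a) -> Lig(l!1,l).Rec(a!1) kp",
    " Rec(b~Y) -> Rec(b~pY) k",
    "end reaction rules"), name = "auto")
  mt <- moleculeTypes(m)
  nms <- vapply(mt, `[[`, "", "name")
  expect_setequal(nms, c("Lig", "Rec"))
  lig <- mt[[match("Lig", nms)]]
  expect_equal(vapply(lig$components, `[[`, 0L, "occurrence"), c(1L, 2L))
  rec <- mt[[match("Rec", nms)]]
  bstates <- rec$components[[match("b", vapply(rec$components, `[[`, "", "name"))]]$states
  expect_setequal(bstates, c("Y", "pY"))
})

test_that("seed species and observables are carried verbatim", {
  m <- parseBNGL(bnglText(
    "begin molecule types", " A(x)", "end molecule types",
    "begin seed species", " A(x) 100", "end seed species",
    "begin observables", " Molecules A_tot A()", "end observables"),
    name = "carry")
  expect_equal(m@seedSpecies, "A(x)")
  expect_equal(m@observables$name, "A_tot")
  expect_equal(m@observables$pattern, "A()")
})

test_that("rule count equals rule statements as written, reversible counted once", {
  for (f in list.files(extdataDir("fceri_synthetic"), full.names = TRUE)) {
    m <- parseBNGL(path = f)
    txt <- readLines(f)
    inRules <- cumsum(grepl("^begin reaction rules", txt)) -
      cumsum(grepl("^end reaction rules", txt))
    nStmt <- sum(inRules == 1L & !grepl("^begin|^\\s*(#|$)", txt))
    expect_identical(length(rules(m)), nStmt)
  }
})

test_that("the parser is total over generated families", {
  for (s in 1:10) {
    fam <- generateFamily(familySpec(seed = s))
    for (nm in names(fam$models))
      expect_s4_class(parseBNGL(text = fam$models[[nm]], name = nm), "Model")
  }
})
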