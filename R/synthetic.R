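# Seeded generator of BNGL model families with a planted common core and
# known edit sets. Ground truth is computed by direct bookkeeping on the
# generator's internal structures, never by the parser or contact-map code,
# so it can serve as an independent oracle for the whole pipeline.

.molPool <- c("Alba", "Brix", "Ceto", "Dorn", "Elix", "Fano", "Gilt", "Hupo",
              "Irix", "Julo", "Kemo", "Lino", "Mopa", "Nilo", "Opal", "Pravo",
              "Quro", "Rixo", "Sulo", "Tivo")
.compPool <- c("a", "b", "g", "d", "u", "k", "r", "l", "m", "p", "q",
               "s2", "s3", "y1", "y2", "y3")
.statePool <- c("U", "P", "A", "I", "X", "Y")

#' Specification of a synthetic model family
#'
#' Describes a planted family: a common core (molecule count, components per
#' molecule, fraction of components carrying states, binding-edge count) and
#' a per-model edit budget of insertions and deletions applied on top of the
#' core. Model 0 receives insertions only, so it is always a strict superset
#' of the core; later models also receive deletions. All randomness is fixed
#' by \code{seed}.
#'
#' @param nModels Number of family members (>= 1).
#' @param nMolecules Molecules in the common core.
#' @param maxComponents Components per core molecule are drawn uniformly
#'   from 1..maxComponents.
#' @param stateFraction Probability that a component carries two internal
#'   states.
#' @param nEdges Binding edges in the core (must not exceed the number of
#'   distinct component pairs).
#' @param edits Named list of per-model edit counts: \code{addMolecules},
#'   \code{addComponents}, \code{addStates}, \code{addEdges},
#'   \code{addSynthesis}, \code{delMolecules}, \code{delComponents},
#'   \code{delStates}, \code{delEdges}. Missing entries default to the
#'   values shown; all counts must be non-negative.
#' @param seed Integer seed.
#' @return A \code{familySpec} list, input to [generateFamily()].
#' @export
familySpec <- function(nModels = 4L, nMolecules = 5L, maxComponents = 3L,
                       stateFraction = 0.4, nEdges = 5L,
                       edits = list(), seed = 1L) {
  defaults <- list(addMolecules = 1L, addComponents = 1L, addStates = 1L,
                   addEdges = 1L, addSynthesis = 1L,
                   delMolecules = 0L, delComponents = 1L, delStates = 1L,
                   delEdges = 1L)
  bad <- setdiff(names(edits), names(defaults))
  if (length(bad)) stop(sprintf("unknown edit budget(s): %s", paste(bad, collapse = ", ")))
  edits <- utils::modifyList(defaults, edits)
  if (any(unlist(edits) < 0L)) stop("edit budgets must be non-negative")
  stopifnot(nModels >= 1L, nMolecules >= 1L, maxComponents >= 1L,
            stateFraction >= 0, stateFraction <= 1, nEdges >= 0L)
  structure(list(nModels = as.integer(nModels),
                 nMolecules = as.integer(nMolecules),
                 maxComponents = as.integer(maxComponents),
                 stateFraction = stateFraction, nEdges = as.integer(nEdges),
                 edits = lapply(edits, as.integer), seed = as.integer(seed)),
            class = "familySpec")
}

## ---- structure bookkeeping ----------------------------------------------

# struct: list(molecules = named list(name -> list(name, components = named
# list(comp -> character states))), edges = list of list(c(mol, comp),
# c(mol, comp)), synthesis = character molecule names)

.structSlots <- function(struct) {
  out <- list()
  for (m in struct$molecules)
    for (cn in names(m$components))
      out[[length(out) + 1L]] <- c(m$name, cn)
  out
}

.structEdgeId <- function(e) {
  edgeId(componentId(e[[1L]][1L], e[[1L]][2L], 1L),
         componentId(e[[2L]][1L], e[[2L]][2L], 1L))
}

.structElements <- function(struct) {
  ids <- character(); rows <- character()
  for (m in struct$molecules) {
    ids <- c(ids, m$name)
    for (cn in names(m$components)) {
      cid <- componentId(m$name, cn, 1L)
      states <- m$components[[cn]]
      ids <- c(ids, cid)
      if (length(states)) {
        ids <- c(ids, paste0(cid, "~", states))
        rows <- c(rows, paste0(cid, "~", states))
      } else rows <- c(rows, cid)
    }
  }
  eids <- vapply(struct$edges, .structEdgeId, "")
  sids <- if (length(struct$synthesis))
    vapply(struct$synthesis, unstructuredId, "", kind = "syn") else character()
  list(elements = unname(sort(c(ids, eids, sids), method = "radix")),
       rows = unname(sort(rows, method = "radix")),
       edges = unname(sort(eids, method = "radix")))
}

.samplePick <- function(x) if (length(x) <= 1L) x[1L] else x[sample.int(length(x), 1L)]

## ---- generation ----------------------------------------------------------

#' Generate a synthetic BNGL model family with ground truth
#'
#' Builds the common core, applies each model's edit budget in a fixed order
#' (molecule, component, state, edge and synthesis insertions, then
#' molecule, component, state and edge deletions), emits syntactically valid
#' BNGL text per model, and records ground truth by direct bookkeeping:
#' per-model element identifier sets, per-pair shared/only sets and
#' similarity factors, the most complete member and the intended family
#' ordering. Identical spec + seed give byte-identical output.
#'
#' @param spec A [familySpec()].
#' @return List with elements \code{models} (named character vector of BNGL
#'   texts), \code{truth} (ground-truth list: \code{elements}, \code{rows},
#'   \code{edges} per model; \code{pairs} with matrices
#'   \code{sharedNodes}, \code{sharedEdges}, \code{nodeFraction},
#'   \code{edgeFraction}, \code{absolute}; \code{sets} with per-pair
#'   shared/only id sets; \code{mostComplete}; \code{ordering};
#'   \code{editLog}) and \code{structs} (internal structures, for
#'   debugging).
#' @examples
#' fam <- generateFamily(familySpec(nModels = 2, seed = 7))
#' names(fam$models)
#' @export
generateFamily <- function(spec) {
  stopifnot(inherits(spec, "familySpec"))
  set.seed(spec$seed %% 2147483647L)

  molNames <- sample(.molPool, min(length(.molPool), spec$nMolecules +
                                     spec$nModels * spec$edits$addMolecules + 2L))
  coreNames <- molNames[seq_len(spec$nMolecules)]
  reserve <- setdiff(molNames, coreNames)

  core <- list(molecules = list(), edges = list(), synthesis = character())
  for (mn in coreNames) {
    nc <- sample.int(spec$maxComponents, 1L)
    comps <- sample(.compPool, nc)
    cl <- list()
    for (cn in comps)
      cl[[cn]] <- if (stats::runif(1) < spec$stateFraction)
        sample(.statePool, 2L) else character()
    core$molecules[[mn]] <- list(name = mn, components = cl)
  }
  slots <- .structSlots(core)
  if (length(slots) >= 2L) {
    cand <- utils::combn(length(slots), 2L)
    if (spec$nEdges > ncol(cand))
      stop(sprintf("infeasible spec: %d edges requested but only %d distinct component pairs exist",
                   spec$nEdges, ncol(cand)))
    pick <- sample.int(ncol(cand), spec$nEdges)
    core$edges <- lapply(pick, function(k)
      list(slots[[cand[1L, k]]], slots[[cand[2L, k]]]))
  } else if (spec$nEdges > 0L) {
    stop("infeasible spec: edges requested but fewer than two components exist")
  }

  structs <- list(); editLog <- list()
  for (i in seq_len(spec$nModels)) {
    st <- core
    log <- list(added = character(), removed = character())
    e <- spec$edits
    applyDeletes <- i > 1L  # model 0 stays a strict superset of the core

    before <- .structElements(st)$elements
    st <- .applyInsertions(st, e, reserve)
    log$added <- setdiff(.structElements(st)$elements, before)
    if (applyDeletes) {
      before <- .structElements(st)$elements
      st <- .applyDeletions(st, e)
      log$removed <- setdiff(before, .structElements(st)$elements)
    }
    nm <- sprintf("m%02d", i - 1L)
    structs[[nm]] <- st
    editLog[[nm]] <- log
  }

  models <- vapply(names(structs), function(nm)
    .emitBNGL(structs[[nm]]), "")
  truth <- .groundTruth(structs)
  truth$editLog <- editLog
  list(models = models, truth = truth, structs = structs)
}

.applyInsertions <- function(st, e, reserve) {
  for (k in seq_len(e$addMolecules)) {
    free <- setdiff(reserve, names(st$molecules))
    if (!length(free)) break
    mn <- .samplePick(free)
    comps <- sample(.compPool, sample.int(2L, 1L))
    cl <- list()
    for (cn in comps) cl[[cn]] <- character()
    st$molecules[[mn]] <- list(name = mn, components = cl)
  }
  for (k in seq_len(e$addComponents)) {
    mn <- .samplePick(names(st$molecules))
    free <- setdiff(.compPool, names(st$molecules[[mn]]$components))
    if (!length(free)) next
    st$molecules[[mn]]$components[[.samplePick(free)]] <- character()
  }
  for (k in seq_len(e$addStates)) {
    slots <- .structSlots(st)
    if (!length(slots)) break
    s <- slots[[.samplePick(seq_along(slots))]]
    cur <- st$molecules[[s[1L]]]$components[[s[2L]]]
    free <- setdiff(.statePool, cur)
    if (!length(free)) next
    st$molecules[[s[1L]]]$components[[s[2L]]] <- c(cur, .samplePick(free))
  }
  for (k in seq_len(e$addEdges)) {
    slots <- .structSlots(st)
    if (length(slots) < 2L) break
    have <- vapply(st$edges, .structEdgeId, "")
    cand <- utils::combn(length(slots), 2L)
    ids <- apply(cand, 2L, function(p)
      .structEdgeId(list(slots[[p[1L]]], slots[[p[2L]]])))
    open <- which(!ids %in% have)
    if (!length(open)) break
    p <- cand[, .samplePick(open)]
    st$edges[[length(st$edges) + 1L]] <- list(slots[[p[1L]]], slots[[p[2L]]])
  }
  for (k in seq_len(e$addSynthesis)) {
    free <- setdiff(names(st$molecules), st$synthesis)
    if (!length(free)) break
    st$synthesis <- c(st$synthesis, .samplePick(free))
  }
  st
}

.applyDeletions <- function(st, e) {
  dropEdgesTouching <- function(st, mn, cn = NULL) {
    keep <- vapply(st$edges, function(ed) {
      for (end in ed)
        if (end[1L] == mn && (is.null(cn) || end[2L] == cn)) return(FALSE)
      TRUE
    }, NA)
    st$edges <- st$edges[keep]
    st
  }
  for (k in seq_len(e$delMolecules)) {
    if (length(st$molecules) <= 1L) break
    mn <- .samplePick(names(st$molecules))
    st$molecules[[mn]] <- NULL
    st <- dropEdgesTouching(st, mn)
    st$synthesis <- setdiff(st$synthesis, mn)
  }
  for (k in seq_len(e$delComponents)) {
    rich <- names(st$molecules)[vapply(st$molecules, function(m)
      length(m$components) >= 2L, NA)]
    if (!length(rich)) break
    mn <- .samplePick(rich)
    cn <- .samplePick(names(st$molecules[[mn]]$components))
    st$molecules[[mn]]$components[[cn]] <- NULL
    st <- dropEdgesTouching(st, mn, cn)
  }
  for (k in seq_len(e$delStates)) {
    slots <- Filter(function(s)
      length(st$molecules[[s[1L]]]$components[[s[2L]]]) >= 1L, .structSlots(st))
    if (!length(slots)) break
    s <- slots[[.samplePick(seq_along(slots))]]
    cur <- st$molecules[[s[1L]]]$components[[s[2L]]]
    st$molecules[[s[1L]]]$components[[s[2L]]] <- setdiff(cur, .samplePick(cur))
  }
  for (k in seq_len(e$delEdges)) {
    if (!length(st$edges)) break
    st$edges <- st$edges[-.samplePick(seq_along(st$edges))]
  }
  st
}

## ---- BNGL emission -------------------------------------------------------

.emitBNGL <- function(st) {
  declFor <- function(m) {
    comps <- vapply(names(m$components), function(cn)
      paste0(cn, paste0(rep("~", length(m$components[[cn]])),
                        m$components[[cn]], collapse = "")), "")
    sprintf("%s(%s)", m$name, paste(comps, collapse = ","))
  }
  speciesFor <- function(m) {
    comps <- vapply(names(m$components), function(cn) {
      s <- m$components[[cn]]
      if (length(s)) paste0(cn, "~", s[1L]) else cn
    }, "")
    sprintf("%s(%s)", m$name, paste(comps, collapse = ","))
  }
  lines <- c("begin model", "begin parameters",
             "  kon 0.1", "  koff 0.01", "  kcat 1.0", "  ksyn 0.5",
             "end parameters", "begin molecule types")
  for (m in st$molecules) lines <- c(lines, paste0("  ", declFor(m)))
  lines <- c(lines, "end molecule types", "begin seed species")
  for (m in st$molecules)
    lines <- c(lines, paste0("  ", speciesFor(m), " 100"))
  lines <- c(lines, "end seed species", "begin observables")
  for (m in st$molecules)
    lines <- c(lines, sprintf("  Molecules %s_total %s()", m$name, m$name))
  lines <- c(lines, "end observables", "begin reaction rules")
  eid <- vapply(st$edges, .structEdgeId, "")
  for (k in order(eid, method = "radix")) {
    e <- st$edges[[k]]
    lines <- c(lines, sprintf("  %s(%s) + %s(%s) <-> %s(%s!1).%s(%s!1) kon, koff",
                              e[[1L]][1L], e[[1L]][2L], e[[2L]][1L], e[[2L]][2L],
                              e[[1L]][1L], e[[1L]][2L], e[[2L]][1L], e[[2L]][2L]))
  }
  for (m in st$molecules) {
    for (cn in names(m$components)) {
      s <- m$components[[cn]]
      if (length(s) >= 2L)
        lines <- c(lines, sprintf("  %s(%s~%s) -> %s(%s~%s) kcat",
                                  m$name, cn, s[1L], m$name, cn, s[2L]))
    }
  }
  for (mn in sort(st$synthesis, method = "radix"))
    lines <- c(lines, sprintf("  0 -> %s ksyn", speciesFor(st$molecules[[mn]])))
  lines <- c(lines, "end reaction rules", "end model")
  paste0(paste(lines, collapse = "\n"), "\n")
}

## ---- ground truth --------------------------------------------------------

.groundTruth <- function(structs) {
  nms <- names(structs)
  n <- length(structs)
  info <- lapply(structs, .structElements)
  sn <- se <- fn <- fe <- ab <- matrix(0, n, n, dimnames = list(nms, nms))
  sets <- list()
  for (i in seq_len(n)) {
    sets[[nms[i]]] <- list()
    for (j in seq_len(n)) {
      a <- info[[i]]; b <- info[[j]]
      ns <- length(intersect(a$rows, b$rows))
      es <- length(intersect(a$edges, b$edges))
      nMin <- min(length(a$rows), length(b$rows))
      eMin <- min(length(a$edges), length(b$edges))
      nf <- if (nMin == 0L) 0 else ns / nMin
      ef <- if (eMin == 0L) 0 else es / eMin
      sn[i, j] <- ns; se[i, j] <- es; fn[i, j] <- nf; fe[i, j] <- ef
      ab[i, j] <- ns * nf + es * ef
      sets[[nms[i]]][[nms[j]]] <- list(
        shared = intersect(a$elements, b$elements),
        onlyA = setdiff(a$elements, b$elements),
        onlyB = setdiff(b$elements, a$elements))
    }
  }
  size <- vapply(info, function(x) length(x$rows) + length(x$edges), 0)
  ref <- order(-size, nms, method = "radix")[1L]
  rest <- setdiff(seq_len(n), ref)
  ordering <- c(ref, rest[order(-ab[rest, ref], nms[rest], method = "radix")])
  list(elements = lapply(info, `[[`, "elements"),
       rows = lapply(info, `[[`, "rows"),
       edges = lapply(info, `[[`, "edges"),
       pairs = list(sharedNodes = sn, sharedEdges = se,
                    nodeFraction = fn, edgeFraction = fe, absolute = ab),
       sets = sets, mostComplete = ref, ordering = ordering,
       scores = ab[, ref])
}

#' Write a generated family to disk
#'
#' Emits one \code{.bngl} file per model plus \code{groundtruth.json}.
#'
#' @param spec A [familySpec()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the generated family (see [generateFamily()]).
#' @export
writeFamily <- function(spec, dir) {
  fam <- generateFamily(spec)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(fam$models))
    writeLines(sub("\n$", "", fam$models[[nm]]), file.path(dir, paste0(nm, ".bngl")))
  jsonlite::write_json(fam$truth[c("elements", "rows", "edges", "mostComplete",
                                   "ordering")],
                       file.path(dir, "groundtruth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(fam)
}
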