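#' Build the contact map of a parsed model
#'
#' Constructs the compact contact-map graph: one molecule node per molecule
#' type (with an implicit whole-molecule component when none is declared),
#' one component node per declared (name, occurrence) pair, state nodes from
#' the declarations, an undirected edge for every bond realized on either
#' side of any rule, and unstructured synthesis/degradation nodes for rules
#' with an empty reactant or product side. Each structure is uniquely
#' identified by a single node or edge regardless of how many rules mention
#' it; the rules contributing to an edge are recorded on the edge.
#'
#' A bond endpoint carries a state qualifier only when the rule writes an
#' explicit state on the bonded component on the side where the bond exists;
#' qualified and unqualified endpoints are distinct for edge identity. A
#' component is flagged modifiable when some rule's multiset of explicit
#' states for that (molecule, component, occurrence) differs between the
#' reactant and product sides (rules whose molecule appears on only one
#' side, i.e. synthesis and degradation, are excluded). Wildcard bonds
#' (\code{!+}, \code{!?}) mark the component as binding but contribute no
#' edge, since the partner is unknown.
#'
#' @param model A [Model-class].
#' @return A [ContactMap-class].
#' @examples
#' m <- parseBNGL(c("begin reaction rules",
#'                  " A(x) + A(x) -> A(x!1).A(x!1) kp",
#'                  "end reaction rules"), name = "dimer")
#' cm <- contactMap(m)
#' elementIds(cm)
#' @export
contactMap <- function(model) {
  stopifnot(methods::is(model, "Model"))
  molecules <- lapply(model@moleculeTypes, function(mt) {
    list(name = mt$name, components = lapply(mt$components, function(cc)
      list(name = cc$name, occurrence = cc$occurrence,
           states = as.character(cc$states),
           modifiable = FALSE, binds = FALSE)))
  })
  names(molecules) <- vapply(molecules, `[[`, "", "name")

  compKey <- function(mol, comp, occ) paste0(mol, "\r", comp, "\r", occ)
  compIndex <- new.env(parent = emptyenv())
  for (mi in seq_along(molecules))
    for (ci in seq_along(molecules[[mi]]$components)) {
      cc <- molecules[[mi]]$components[[ci]]
      assign(compKey(molecules[[mi]]$name, cc$name, cc$occurrence),
             c(mi, ci), envir = compIndex)
    }

  edgeEnv <- new.env(parent = emptyenv())  # id -> list(end1, end2, rules)
  unstr <- list()
  nWild <- 0L
  markFlag <- function(mol, comp, occ, what) {
    k <- compKey(mol, comp, occ)
    if (!exists(k, envir = compIndex)) return(invisible())
    ix <- get(k, envir = compIndex)
    molecules[[ix[1L]]]$components[[ix[2L]]][[what]] <<- TRUE
  }

  for (r in model@rules) {
    rid <- if (!is.na(r$label)) r$label else sprintf("R%d", r$index)
    sideMols <- lapply(list(r$reactants, r$products), function(side) {
      unique(unlist(lapply(side, function(cplx)
        vapply(cplx, `[[`, "", "name"))))
    })
    stateMultiset <- list(list(), list())

    for (si in 1:2) {
      side <- if (si == 1L) r$reactants else r$products
      bonds <- list()  # tag -> list of endpoints
      for (cplx in side) {
        for (mol in cplx) {
          for (comp in mol$components) {
            if (!is.na(comp$state)) {
              k <- compKey(mol$name, comp$name, comp$occurrence)
              stateMultiset[[si]][[k]] <- c(stateMultiset[[si]][[k]], comp$state)
            }
            if (is.na(comp$bond)) next
            if (comp$bond %in% c("+", "?")) {
              nWild <- nWild + 1L
              markFlag(mol$name, comp$name, comp$occurrence, "binds")
            } else {
              ep <- endpointId(mol$name, comp$name, comp$occurrence, comp$state)
              bonds[[comp$bond]] <- c(bonds[[comp$bond]], ep)
              markFlag(mol$name, comp$name, comp$occurrence, "binds")
            }
          }
        }
      }
      for (tag in names(bonds)) {
        ep <- sort(bonds[[tag]], method = "radix")
        id <- paste0("{", ep[1L], "|", ep[2L], "}")
        cur <- if (exists(id, envir = edgeEnv)) get(id, envir = edgeEnv)
               else list(end1 = ep[1L], end2 = ep[2L], rules = character())
        cur$rules <- union(cur$rules, rid)
        assign(id, cur, envir = edgeEnv)
      }
    }

    # modifiability: explicit-state multisets differ between sides, for
    # molecules present on both sides
    both <- intersect(sideMols[[1L]], sideMols[[2L]])
    keys <- union(names(stateMultiset[[1L]]), names(stateMultiset[[2L]]))
    for (k in keys) {
      molName <- strsplit(k, "\r", fixed = TRUE)[[1L]][1L]
      if (!molName %in% both) next
      a <- sort(as.character(stateMultiset[[1L]][[k]]))
      b <- sort(as.character(stateMultiset[[2L]][[k]]))
      if (!identical(a, b)) {
        parts <- strsplit(k, "\r", fixed = TRUE)[[1L]]
        markFlag(parts[1L], parts[2L], as.integer(parts[3L]), "modifiable")
      }
    }

    if (r$isSynthesis)
      for (mn in sideMols[[2L]]) unstr[[unstructuredId(mn, "syn")]] <-
        list(kind = "syn", molecule = mn)
    if (r$isDegradation)
      for (mn in sideMols[[1L]]) unstr[[unstructuredId(mn, "deg")]] <-
        list(kind = "deg", molecule = mn)
  }

  if (nWild > 0L)
    warning(sprintf("model '%s': %d bound-wildcard bond(s) (!+/!?) contribute no contact-map edge",
                    model@name, nWild), call. = FALSE)

  eids <- sort(ls(edgeEnv), method = "radix")
  edges <- data.frame(
    id = eids,
    end1 = vapply(eids, function(i) get(i, envir = edgeEnv)$end1, ""),
    end2 = vapply(eids, function(i) get(i, envir = edgeEnv)$end2, ""),
    stringsAsFactors = FALSE, row.names = NULL)
  edges$rules <- lapply(eids, function(i) get(i, envir = edgeEnv)$rules)

  uids <- if (length(unstr)) sort(names(unstr), method = "radix") else character()
  unstructured <- data.frame(
    id = uids,
    kind = vapply(uids, function(i) unstr[[i]]$kind, ""),
    molecule = vapply(uids, function(i) unstr[[i]]$molecule, ""),
    stringsAsFactors = FALSE, row.names = NULL)

  methods::new("ContactMap", modelName = model@name,
               molecules = unname(molecules), edges = edges,
               unstructured = unstructured)
}

#' Canonical element identifiers of a contact map
#'
#' Returns the identifiers of every element of the map: molecules,
#' components, states, unstructured synthesis/degradation nodes, and edges
#' (see [elementKind()] for the grammar). String equality of these
#' identifiers defines element equality across models and is the unit of all
#' comparison.
#'
#' @param x A [ContactMap-class].
#' @param ... Unused.
#' @return Sorted character vector of element identifiers.
#' @seealso [contactMap()], [compareSimilarities()]
#' @export
#' @rdname elementIds
setMethod("elementIds", "ContactMap", function(x, ...) {
  out <- character()
  for (m in x@molecules) {
    out <- c(out, m$name)
    for (cc in m$components) {
      cid <- componentId(m$name, cc$name, cc$occurrence)
      out <- c(out, cid)
      if (length(cc$states)) out <- c(out, paste0(cid, "~", cc$states))
    }
  }
  sort(c(out, x@unstructured$id, x@edges$id), method = "radix")
})

#' Edge identifiers of a contact map
#'
#' @param x A [ContactMap-class].
#' @param ... Unused.
#' @return Sorted character vector of canonical edge identifiers.
#' @export
#' @rdname edgeIds
setMethod("edgeIds", "ContactMap", function(x, ...) {
  sort(x@edges$id, method = "radix")
})

#' Summary counts of a contact map
#'
#' Returns the element counts of a contact map: molecules, components,
#' states, modifiable components, edges, unstructured nodes, the visual node
#' count (molecules + components + states + unstructured nodes, i.e. the
#' nodes drawn in a panel) and the adjacency-matrix row count (every state
#' plus every stateless component, the "nodes" of the similarity metric).
#'
#' @param x A [ContactMap-class].
#' @param ... Unused.
#' @return Named integer vector with elements \code{nMolecules},
#'   \code{nComponents}, \code{nStates}, \code{nModifiable}, \code{nEdges},
#'   \code{nUnstructured}, \code{nVisualNodes}, \code{nMatrixRows}.
#' @export
#' @rdname cmapStats
setMethod("cmapStats", "ContactMap", function(x, ...) {
  nMol <- length(x@molecules)
  nComp <- 0L; nState <- 0L; nMod <- 0L; nRows <- 0L
  for (m in x@molecules) {
    for (cc in m$components) {
      nComp <- nComp + 1L
      nState <- nState + length(cc$states)
      if (isTRUE(cc$modifiable)) nMod <- nMod + 1L
      nRows <- nRows + max(1L, length(cc$states))
    }
  }
  c(nMolecules = nMol, nComponents = nComp, nStates = nState,
    nModifiable = nMod, nEdges = nrow(x@edges),
    nUnstructured = nrow(x@unstructured),
    nVisualNodes = nMol + nComp + nState + nrow(x@unstructured),
    nMatrixRows = nRows)
})
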