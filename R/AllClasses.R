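#' @import methods
NULL

#' Parsed rule-based model
#'
#' Container for a rule-based model parsed from BioNetGen language (BNGL)
#' text: the declared (or auto-declared) molecule types, the reaction rules,
#' and the seed species and observables blocks (carried verbatim, never
#' interpreted).
#'
#' @slot name Model name (usually the file stem).
#' @slot moleculeTypes Ordered list of molecule type declarations. Each is a
#'   list with elements \code{name} and \code{components}; each component is a
#'   list with \code{name}, \code{occurrence} (1-based index among same-named
#'   components of the molecule) and \code{states} (character vector, possibly
#'   empty).
#' @slot rules Ordered list of reaction rules. Each is a list with
#'   \code{label}, \code{reactants}, \code{products} (lists of complexes;
#'   a complex is a list of pattern molecules), \code{reversible},
#'   \code{rates} (character, never evaluated), \code{isSynthesis} and
#'   \code{isDegradation}.
#' @slot seedSpecies Character vector of seed species pattern strings
#'   (carried, not interpreted).
#' @slot observables Data frame with columns \code{name} and \code{pattern}.
#' @slot sourcePath Path the model was read from ("" when parsed from text).
#'
#' @seealso [parseBNGL()], [contactMap()]
#' @export
setClass("Model", representation(
  name = "character",
  moleculeTypes = "list",
  rules = "list",
  seedSpecies = "character",
  observables = "data.frame",
  sourcePath = "character"
))

setValidity("Model", function(object) {
  msgs <- character()
  nms <- vapply(object@moleculeTypes, `[[`, "", "name")
  if (anyDuplicated(nms))
    msgs <- c(msgs, sprintf("duplicate molecule type name(s): %s",
                            paste(unique(nms[duplicated(nms)]), collapse = ", ")))
  for (mt in object@moleculeTypes) {
    if (length(mt$components) < 1L)
      msgs <- c(msgs, sprintf("molecule '%s' has no components", mt$name))
    key <- vapply(mt$components, `[[`, "", "name")
    for (k in unique(key)) {
      occ <- sort(vapply(mt$components[key == k], `[[`, 0L, "occurrence"))
      if (!identical(occ, seq_along(occ)))
        msgs <- c(msgs, sprintf("molecule '%s': occurrences of component '%s' not contiguous from 1",
                                mt$name, k))
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Contact map of a rule-based model
#'
#' The compact graph abstraction of a rule-based model: one molecule node per
#' molecule type, containing one component node per declared (name,
#' occurrence) pair with its state nodes, plus one undirected edge per
#' possible binding interaction realized by the rules and unstructured
#' synthesis/degradation nodes. Every structure appears exactly once
#' regardless of how many rules mention it.
#'
#' @slot modelName Name of the source model.
#' @slot molecules List of molecule nodes; each a list with \code{name} and
#'   \code{components} (list of component nodes with \code{name},
#'   \code{occurrence}, \code{states}, \code{modifiable}, \code{binds}).
#' @slot edges Data frame with columns \code{id} (canonical edge identifier),
#'   \code{end1}, \code{end2} (endpoint identifiers, lexicographically
#'   sorted) and \code{rules} (list column of contributing rule labels).
#' @slot unstructured Data frame with columns \code{id}, \code{kind}
#'   (\code{"syn"} or \code{"deg"}) and \code{molecule}.
#'
#' @seealso [contactMap()], [elementIds()], [cmapStats()]
#' @export
setClass("ContactMap", representation(
  modelName = "character",
  molecules = "list",
  edges = "data.frame",
  unstructured = "data.frame"
))

setValidity("ContactMap", function(object) {
  msgs <- character()
  comp <- character()
  for (m in object@molecules) {
    if (length(m$components) < 1L)
      msgs <- c(msgs, sprintf("molecule node '%s' has no component nodes", m$name))
    for (cc in m$components) {
      comp <- c(comp, componentId(m$name, cc$name, cc$occurrence))
      if (isTRUE(cc$modifiable) && length(cc$states) == 0L)
        msgs <- c(msgs, sprintf("component %s is modifiable but has no states",
                                componentId(m$name, cc$name, cc$occurrence)))
    }
  }
  if (anyDuplicated(comp))
    msgs <- c(msgs, "duplicate component nodes")
  ep <- sub("~[A-Za-z0-9_]+$", "", c(object@edges$end1, object@edges$end2))
  bad <- setdiff(ep, comp)
  if (length(bad))
    msgs <- c(msgs, sprintf("edge endpoint(s) not in contact map: %s",
                            paste(unique(bad), collapse = ", ")))
  if (length(msgs)) msgs else TRUE
})

#' Stored element positions for layout stabilization
#'
#' A persistent assignment of (x, y) coordinates (abstract layout units) to
#' contact-map elements, keyed by canonical element identifier. Used to pin
#' shared elements to common positions across a family of models and to share
#' hand-tuned layouts alongside model files.
#'
#' @slot name Model or family name the layout belongs to.
#' @slot positions Data frame with columns \code{id}, \code{x}, \code{y}.
#' @slot version Format version marker.
#'
#' @seealso [readLayoutFile()], [writeLayoutFile()], [stabilizeLayouts()]
#' @export
setClass("StoredLayout", representation(
  name = "character",
  positions = "data.frame",
  version = "character"
))

setValidity("StoredLayout", function(object) {
  p <- object@positions
  if (!all(c("id", "x", "y") %in% names(p)))
    return("positions must have columns id, x, y")
  if (nrow(p) && (!all(is.finite(p$x)) || !all(is.finite(p$y))))
    return("all coordinates must be finite")
  if (anyDuplicated(p$id)) return("duplicate element ids in layout")
  TRUE
})

#' Concrete node coordinates for one contact map
#'
#' A fully resolved two-level layout: molecule boxes (center + extent),
#' component rectangles inside their molecule box, state rectangles stacked
#' beside their component, and unstructured-node positions. Produced by
#' [forceLayout()] / [stabilizeLayouts()].
#'
#' @slot modelName Name of the laid-out model.
#' @slot nodes Data frame with columns \code{id}, \code{kind}
#'   (molecule/component/state/unstructured), \code{molecule}, \code{x},
#'   \code{y} (center), \code{w}, \code{h} (extent) and \code{pinned}.
#' @export
setClass("CMapLayout", representation(
  modelName = "character",
  nodes = "data.frame"
))

#' Pairwise similarity matrices for a model family
#'
#' The four similarity matrices over a family of contact maps plus their
#' combined absolute score: shared adjacency-row ("node") counts, shared edge
#' counts, the fraction of the smaller graph's rows shared, the fraction of
#' the smaller graph's edges shared, and the absolute score
#' \eqn{S = N_s f_N + E_s f_E}.
#'
#' @slot modelNames Model names (row/column labels of all matrices).
#' @slot sharedNodes Integer matrix of shared adjacency-row counts.
#' @slot sharedEdges Integer matrix of shared edge counts.
#' @slot nodeFraction Numeric matrix in [0, 1].
#' @slot edgeFraction Numeric matrix in [0, 1].
#' @slot absolute Numeric matrix of combined scores.
#' @seealso [similarityMatrices()], [absoluteSimilarity()]
#' @export
setClass("SimilarityMatrices", representation(
  modelNames = "character",
  sharedNodes = "matrix",
  sharedEdges = "matrix",
  nodeFraction = "matrix",
  edgeFraction = "matrix",
  absolute = "matrix"
))

setValidity("SimilarityMatrices", function(object) {
  n <- length(object@modelNames)
  for (s in c("sharedNodes", "sharedEdges", "nodeFraction", "edgeFraction", "absolute")) {
    m <- slot(object, s)
    if (!identical(dim(m), c(n, n))) return(sprintf("%s must be %d x %d", s, n, n))
    if (!isTRUE(all.equal(m, t(m)))) return(sprintf("%s must be symmetric", s))
  }
  if (any(object@nodeFraction < 0 | object@nodeFraction > 1) ||
      any(object@edgeFraction < 0 | object@edgeFraction > 1))
    return("fractions must lie in [0, 1]")
  TRUE
})

#' Family ordering relative to the most complete model
#'
#' The small-multiples ordering of a family: the most complete model (largest
#' row + edge count) first, the remaining models in order of decreasing
#' absolute similarity to it.
#'
#' @slot modelNames Model names in original (input) order.
#' @slot reference Index (into \code{modelNames}) of the most complete model.
#' @slot ordering Integer permutation of \code{seq_along(modelNames)};
#'   \code{ordering[1] == reference}.
#' @slot scores Absolute similarity of each model (original order) to the
#'   reference.
#' @seealso [sortFamily()], [mostComplete()]
#' @export
setClass("FamilyOrdering", representation(
  modelNames = "character",
  reference = "integer",
  ordering = "integer",
  scores = "numeric"
))

setValidity("FamilyOrdering", function(object) {
  n <- length(object@modelNames)
  if (!identical(sort(object@ordering), seq_len(n)))
    return("ordering must be a permutation of the model indices")
  if (object@ordering[1L] != object@reference)
    return("reference must occupy position 1")
  if (is.unsorted(-object@scores[object@ordering]))
    return("scores must be non-increasing along the ordering")
  TRUE
})

#' Result of a pairwise or family-wide element comparison
#'
#' Element-identifier sets behind the similarity/difference overlays: the
#' shared set for a similarities comparison, the only-in-A / only-in-B sets
#' for a differences comparison, or a per-model membership vector for a
#' family-wide element search.
#'
#' @slot mode One of \code{"similarities"}, \code{"differences"},
#'   \code{"find"}.
#' @slot modelNames Names of the models involved.
#' @slot shared Character vector of shared element ids (similarities mode).
#' @slot onlyA,onlyB Character vectors of difference element ids
#'   (differences mode).
#' @slot membership Named logical vector (find mode).
#' @seealso [compareSimilarities()], [compareDifferences()], [findElement()]
#' @export
setClass("ComparisonResult", representation(
  mode = "character",
  modelNames = "character",
  shared = "character",
  onlyA = "character",
  onlyB = "character",
  membership = "logical"
))
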