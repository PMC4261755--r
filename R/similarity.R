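#' Adjacency-matrix rows of a contact map
#'
#' The similarity metric is defined over an adjacency-matrix abstraction of
#' the contact map, built bottom-up from the finest granularity: every state
#' is guaranteed a row/column, and a component is included as a row/column
#' only if it has no states already included. Molecules contribute only
#' through their components (a molecule always has at least one component,
#' possibly the implicit whole-molecule component).
#'
#' @param x A [ContactMap-class].
#' @param ... Unused.
#' @return Sorted character vector of row identifiers (state ids plus
#'   stateless-component ids).
#' @examples
#' m <- parseBNGL("begin molecule types\n A(x,y~U~P)\nend molecule types")
#' matrixRows(contactMap(m))
#' @export
#' @rdname matrixRows
setMethod("matrixRows", "ContactMap", function(x, ...) {
  out <- character()
  for (m in x@molecules) {
    for (cc in m$components) {
      cid <- componentId(m$name, cc$name, cc$occurrence)
      out <- c(out, if (length(cc$states)) paste0(cid, "~", cc$states) else cid)
    }
  }
  sort(out, method = "radix")
})

#' Boolean adjacency matrix of a contact map
#'
#' The symmetric boolean matrix over [matrixRows()]: entry (i, j) is
#' \code{TRUE} iff a contact-map edge joins the components owning rows i and
#' j; the diagonal encodes self-edges (homodimerization). An unqualified
#' edge endpoint covers all rows of its component; a state-qualified
#' endpoint covers only that state's row.
#'
#' @param cmap A [ContactMap-class].
#' @return Logical matrix with row/column names from [matrixRows()].
#' @export
adjacencyMatrix <- function(cmap) {
  rows <- matrixRows(cmap)
  A <- matrix(FALSE, length(rows), length(rows), dimnames = list(rows, rows))
  epRows <- function(ep) {
    if (ep %in% rows) return(ep)               # stateless component or state
    rows[startsWith(rows, paste0(ep, "~"))]    # unqualified, component has states
  }
  for (k in seq_len(nrow(cmap@edges))) {
    r1 <- epRows(cmap@edges$end1[k])
    r2 <- epRows(cmap@edges$end2[k])
    A[r1, r2] <- TRUE
    A[r2, r1] <- TRUE
  }
  A
}

#' Shared node and edge counts of two contact maps
#'
#' Counts the adjacency-matrix rows ("nodes") and the edges whose canonical
#' identifiers are string-identical in the two maps (synonyms are not
#' matched). Symmetric in its arguments.
#'
#' @param a,b [ContactMap-class] objects built under identical conventions.
#' @param countUnstructured Count the attachments of unstructured
#'   synthesis/degradation nodes as edges? Default \code{FALSE}: they are
#'   not binding interactions.
#' @return Named integer vector \code{c(nodes, edges)}.
#' @seealso [sharedFractions()], [absoluteSimilarity()]
#' @export
sharedCounts <- function(a, b, countUnstructured = FALSE) {
  c(nodes = length(intersect(matrixRows(a), matrixRows(b))),
    edges = length(intersect(.metricEdges(a, countUnstructured),
                             .metricEdges(b, countUnstructured))))
}

.metricEdges <- function(cmap, countUnstructured = FALSE) {
  e <- cmap@edges$id
  if (countUnstructured) e <- c(e, cmap@unstructured$id)
  e
}

#' Smaller-graph node and edge fractions
#'
#' The fraction of the smaller graph's adjacency rows (respectively edges)
#' present in the larger graph; "smaller" is judged independently for nodes
#' and edges. If graph G is a subgraph of graph H both fractions are 1
#' regardless of the size of H. When the smaller graph has no rows (or no
#' edges) the corresponding fraction is defined as 0; the matching count
#' factor of the absolute score is then also 0, so the score is unaffected.
#'
#' @inheritParams sharedCounts
#' @return Named numeric vector \code{c(nodes, edges)}, values in [0, 1].
#' @export
sharedFractions <- function(a, b, countUnstructured = FALSE) {
  sc <- sharedCounts(a, b, countUnstructured)
  nA <- length(matrixRows(a)); nB <- length(matrixRows(b))
  eA <- length(.metricEdges(a, countUnstructured))
  eB <- length(.metricEdges(b, countUnstructured))
  frac <- function(shared, small) if (small == 0L) 0 else shared / small
  c(nodes = frac(sc[["nodes"]], min(nA, nB)),
    edges = frac(sc[["edges"]], min(eA, eB)))
}

#' Absolute similarity score of two contact maps
#'
#' The combined score
#' \deqn{S(A, B) = N_s \cdot f_N + E_s \cdot f_E,}
#' where \eqn{N_s, E_s} are the shared node and edge counts and
#' \eqn{f_N, f_E} the smaller-graph node and edge fractions. The score
#' rewards both large absolute overlap and subgraph containment:
#' \eqn{S(A, A)} equals rows(A) + edges(A), and a disjoint pair scores 0.
#'
#' @inheritParams sharedCounts
#' @return Numeric scalar.
#' @examples
#' m <- parseBNGL("begin molecule types\n A(x,y~U~P)\nend molecule types")
#' cm <- contactMap(m)
#' absoluteSimilarity(cm, cm)  # = rows + edges
#' @export
absoluteSimilarity <- function(a, b, countUnstructured = FALSE) {
  sc <- sharedCounts(a, b, countUnstructured)
  fr <- sharedFractions(a, b, countUnstructured)
  unname(sc[["nodes"]] * fr[["nodes"]] + sc[["edges"]] * fr[["edges"]])
}

#' Pairwise similarity matrices for a family of contact maps
#'
#' Precomputes, for every unordered pair of models, the four similarity
#' matrices (shared node count, shared edge count, node fraction, edge
#' fraction) and the combined absolute score. All matrices are symmetric by
#' construction; the diagonal of the absolute matrix equals each model's
#' rows + edges.
#'
#' @param family List of [ContactMap-class] objects (length >= 1).
#' @param countUnstructured See [sharedCounts()].
#' @return A [SimilarityMatrices-class].
#' @export
similarityMatrices <- function(family, countUnstructured = FALSE) {
  stopifnot(length(family) >= 1L)
  n <- length(family)
  nms <- vapply(family, modelName, "")
  sn <- se <- fn <- fe <- ab <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in i:n) {
      sc <- sharedCounts(family[[i]], family[[j]], countUnstructured)
      fr <- sharedFractions(family[[i]], family[[j]], countUnstructured)
      sn[i, j] <- sn[j, i] <- sc[["nodes"]]
      se[i, j] <- se[j, i] <- sc[["edges"]]
      fn[i, j] <- fn[j, i] <- fr[["nodes"]]
      fe[i, j] <- fe[j, i] <- fr[["edges"]]
      ab[i, j] <- ab[j, i] <- sc[["nodes"]] * fr[["nodes"]] + sc[["edges"]] * fr[["edges"]]
    }
  }
  methods::new("SimilarityMatrices", modelNames = nms,
               sharedNodes = sn, sharedEdges = se,
               nodeFraction = fn, edgeFraction = fe, absolute = ab)
}

#' Most complete model of a family
#'
#' The most complete graph is assumed to be the one with the greatest
#' combined number of adjacency rows and edges, reflecting the iterative
#' growth of model families. Ties are broken by model name, ascending.
#'
#' @inheritParams similarityMatrices
#' @return Integer index into \code{family}.
#' @export
mostComplete <- function(family, countUnstructured = FALSE) {
  stopifnot(length(family) >= 1L)
  size <- vapply(family, function(cm)
    length(matrixRows(cm)) + length(.metricEdges(cm, countUnstructured)), 0)
  nms <- vapply(family, modelName, "")
  ord <- order(-size, nms, method = "radix")
  ord[1L]
}

#' Sort a family relative to its most complete model
#'
#' Produces the row-wise small-multiples ordering: the most complete model
#' first, then the remaining models by decreasing absolute similarity to it,
#' with ties broken by model name. The ordering is invariant under
#' permutation of the input family.
#'
#' @inheritParams similarityMatrices
#' @return A [FamilyOrdering-class].
#' @export
sortFamily <- function(family, countUnstructured = FALSE) {
  stopifnot(length(family) >= 1L)
  nms <- vapply(family, modelName, "")
  ref <- mostComplete(family, countUnstructured)
  scores <- vapply(family, function(cm)
    absoluteSimilarity(cm, family[[ref]], countUnstructured), 0)
  rest <- setdiff(seq_along(family), ref)
  ordering <- c(ref, rest[order(-scores[rest], nms[rest], method = "radix")])
  methods::new("FamilyOrdering", modelNames = nms, reference = as.integer(ref),
               ordering = as.integer(ordering), scores = scores)
}
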