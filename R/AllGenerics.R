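#' @rdname elementIds
#' @export
setGeneric("elementIds", function(x, ...) standardGeneric("elementIds"))

#' @rdname cmapStats
#' @export
setGeneric("cmapStats", function(x, ...) standardGeneric("cmapStats"))

#' @rdname matrixRows
#' @export
setGeneric("matrixRows", function(x, ...) standardGeneric("matrixRows"))

#' @rdname edgeIds
#' @export
setGeneric("edgeIds", function(x, ...) standardGeneric("edgeIds"))

#' Model and result accessors
#'
#' Accessors for the core classes: \code{modelName()} returns the name of a
#' [Model-class], [ContactMap-class] or [CMapLayout-class]; \code{rules()} and
#' \code{moleculeTypes()} return the rule and molecule type lists of a
#' [Model-class]; \code{positions()} returns the coordinate table of a
#' [StoredLayout-class] or [CMapLayout-class].
#'
#' @param x Object.
#' @param ... Unused.
#' @return \code{modelName()}: a character scalar. \code{rules()},
#'   \code{moleculeTypes()}: a list. \code{positions()}: a data frame.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("modelName", function(x, ...) standardGeneric("modelName"))

#' @rdname accessors
#' @export
setGeneric("rules", function(x, ...) standardGeneric("rules"))

#' @rdname accessors
#' @export
setGeneric("moleculeTypes", function(x, ...) standardGeneric("moleculeTypes"))

#' @rdname accessors
#' @export
setGeneric("positions", function(x, ...) standardGeneric("positions"))

#' @rdname accessors
#' @export
setMethod("modelName", "Model", function(x, ...) x@name)

#' @rdname accessors
#' @export
setMethod("modelName", "ContactMap", function(x, ...) x@modelName)

#' @rdname accessors
#' @export
setMethod("modelName", "CMapLayout", function(x, ...) x@modelName)

#' @rdname accessors
#' @export
setMethod("rules", "Model", function(x, ...) x@rules)

#' @rdname accessors
#' @export
setMethod("moleculeTypes", "Model", function(x, ...) x@moleculeTypes)

#' @rdname accessors
#' @export
setMethod("positions", "StoredLayout", function(x, ...) x@positions)

#' @rdname accessors
#' @export
setMethod("positions", "CMapLayout", function(x, ...) x@nodes[, c("id", "x", "y")])

setMethod("show", "Model", function(object) {
  cat(sprintf("Model '%s': %d molecule type(s), %d rule(s), %d seed species, %d observable(s)\n",
              object@name, length(object@moleculeTypes), length(object@rules),
              length(object@seedSpecies), nrow(object@observables)))
  for (mt in object@moleculeTypes)
    cat("  ", formatMoleculeType(mt), "\n", sep = "")
})

setMethod("show", "ContactMap", function(object) {
  s <- cmapStats(object)
  cat(sprintf("ContactMap '%s': %d molecule(s), %d component(s), %d state(s), %d edge(s)\n",
              object@modelName, s["nMolecules"], s["nComponents"], s["nStates"], s["nEdges"]))
  cat(sprintf("  modifiable components: %d; unstructured nodes: %d; matrix rows: %d\n",
              s["nModifiable"], s["nUnstructured"], s["nMatrixRows"]))
})

setMethod("show", "StoredLayout", function(object) {
  cat(sprintf("StoredLayout '%s' (%s): %d position(s)\n",
              object@name, object@version, nrow(object@positions)))
})

setMethod("show", "CMapLayout", function(object) {
  cat(sprintf("CMapLayout '%s': %d node(s), %d pinned\n",
              object@modelName, nrow(object@nodes), sum(object@nodes$pinned)))
})

setMethod("show", "SimilarityMatrices", function(object) {
  cat(sprintf("SimilarityMatrices over %d model(s)\n", length(object@modelNames)))
  cat("absolute scores:\n")
  m <- object@absolute
  dimnames(m) <- list(object@modelNames, object@modelNames)
  print(round(m, 3))
})

setMethod("show", "FamilyOrdering", function(object) {
  cat(sprintf("FamilyOrdering: reference '%s'\n", object@modelNames[object@reference]))
  for (i in seq_along(object@ordering)) {
    k <- object@ordering[i]
    cat(sprintf("  %2d. %s (score %.3f)\n", i, object@modelNames[k], object@scores[k]))
  }
})

setMethod("show", "ComparisonResult", function(object) {
  if (object@mode == "find") {
    cat(sprintf("ComparisonResult (find): present in %d/%d model(s)\n",
                sum(object@membership), length(object@membership)))
  } else if (object@mode == "similarities") {
    cat(sprintf("ComparisonResult (similarities) %s vs %s: %d shared element(s)\n",
                object@modelNames[1], object@modelNames[2], length(object@shared)))
  } else {
    cat(sprintf("ComparisonResult (differences) %s vs %s: %d only in first, %d only in second\n",
                object@modelNames[1], object@modelNames[2],
                length(object@onlyA), length(object@onlyB)))
  }
})
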