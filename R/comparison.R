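#' Shared elements of two contact maps
#'
#' Computes the set of elements — molecules, components, states,
#' unstructured nodes, and edges — whose canonical identifiers appear in
#' both maps. This is the data behind a similarity overlay. A state element
#' is shared only when molecule, component, occurrence and state label all
#' match; a component element is shared even when its state lists differ
#' (the differing states then show up as difference elements). An edge is
#' shared only when both endpoints, including any state qualifiers, match.
#'
#' @param a,b [ContactMap-class] objects built under identical conventions.
#' @return A [ComparisonResult-class] with mode \code{"similarities"}.
#' @seealso [compareDifferences()], [findElement()]
#' @export
compareSimilarities <- function(a, b) {
  methods::new("ComparisonResult", mode = "similarities",
               modelNames = c(modelName(a), modelName(b)),
               shared = sort(intersect(elementIds(a), elementIds(b)), method = "radix"),
               onlyA = character(), onlyB = character(), membership = logical())
}

#' Difference elements of two contact maps
#'
#' Computes the elements present in one model but not the other, in both
#' directions. When one map is a complete subgraph of the other, its
#' difference set is empty (the empty-overlay case of a pairwise
#' comparison). Together with [compareSimilarities()] the results partition
#' each model's element set: shared plus only-in-A equals the elements of A.
#'
#' @inheritParams compareSimilarities
#' @return A [ComparisonResult-class] with mode \code{"differences"}.
#' @export
compareDifferences <- function(a, b) {
  ea <- elementIds(a); eb <- elementIds(b)
  methods::new("ComparisonResult", mode = "differences",
               modelNames = c(modelName(a), modelName(b)),
               shared = character(),
               onlyA = sort(setdiff(ea, eb), method = "radix"),
               onlyB = sort(setdiff(eb, ea), method = "radix"),
               membership = logical())
}

#' Locate a single element across a model family
#'
#' Tests each family member for the presence of one element identifier —
#' useful for finding which models contain a problematic rule's edge or a
#' binding site of interest. An identifier present nowhere yields all-FALSE;
#' a malformed identifier is an error citing the grammar.
#'
#' @param family List of [ContactMap-class] objects.
#' @param id Canonical element identifier (see [elementKind()]).
#' @return A [ComparisonResult-class] with mode \code{"find"}; its
#'   \code{membership} slot is a named logical vector, one entry per model.
#' @export
findElement <- function(family, id) {
  elementKind(id)  # validates; errors on malformed ids
  member <- vapply(family, function(cm) id %in% elementIds(cm), NA)
  names(member) <- vapply(family, modelName, "")
  methods::new("ComparisonResult", mode = "find",
               modelNames = names(member),
               shared = character(), onlyA = character(), onlyB = character(),
               membership = member)
}

#' Write or read a machine-readable comparison report
#'
#' The report format consumed by the render module as highlight sets:
#' section headers \code{[shared]}, \code{[only <model>]} or
#' \code{[membership]}, followed by \code{kind<TAB>id} lines (or
#' \code{model<TAB>TRUE/FALSE} lines for a find report).
#'
#' @param result A [ComparisonResult-class].
#' @param path Optional output file.
#' @param text Report text or lines (for \code{readComparisonReport}).
#' @return \code{formatComparisonReport()}: report text (invisibly when
#'   \code{path} given). \code{readComparisonReport()}: a named list of
#'   character vectors of element ids, one per section.
#' @export
formatComparisonReport <- function(result, path = NULL) {
  stopifnot(methods::is(result, "ComparisonResult"))
  lines <- c(sprintf("# cmapkit comparison report"),
             sprintf("mode\t%s", result@mode),
             sprintf("models\t%s", paste(result@modelNames, collapse = "\t")))
  sec <- function(name, ids) {
    if (result@mode == "find") return(character())
    c(sprintf("[%s]", name), sprintf("%s\t%s",
                                     vapply(ids, elementKind, ""), ids))
  }
  if (result@mode == "similarities") {
    lines <- c(lines, sec("shared", result@shared))
  } else if (result@mode == "differences") {
    lines <- c(lines,
               sec(paste("only", result@modelNames[1L]), result@onlyA),
               sec(paste("only", result@modelNames[2L]), result@onlyB))
  } else {
    lines <- c(lines, "[membership]",
               sprintf("%s\t%s", names(result@membership),
                       ifelse(result@membership, "TRUE", "FALSE")))
  }
  text <- paste0(paste(lines, collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(text))
  }
  text
}

#' @rdname formatComparisonReport
#' @export
readComparisonReport <- function(text = NULL, path = NULL) {
  if (!is.null(path)) text <- readLines(path, warn = FALSE)
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  out <- list()
  current <- NULL
  for (ln in lines) {
    t <- trimws(ln)
    if (!nzchar(t) || startsWith(t, "#")) next
    if (grepl("^\\[.*\\]$", t)) {
      current <- substr(t, 2L, nchar(t) - 1L)
      out[[current]] <- character()
      next
    }
    if (is.null(current)) next  # mode / models header lines
    tok <- strsplit(t, "\t", fixed = TRUE)[[1L]]
    out[[current]] <- c(out[[current]], tok[length(tok)])
  }
  out
}
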