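# Canonical element identifier grammar (public, stable):
#   molecule      M
#   component     M.c#k        (k = 1-based occurrence among same-named
#                               components of molecule M)
#   state         M.c#k~s
#   edge          {EP|EP}      endpoints sorted lexicographically; an
#                               endpoint is M.c#k or M.c#k~s
#   unstructured  M.@syn / M.@deg
# String equality of identifiers defines element equality across models.

.nameRe <- "[A-Za-z_][A-Za-z0-9_]*"
.tokRe <- "[A-Za-z0-9_]+"
.endpointRe <- sprintf("%s\\.%s#[0-9]+(~%s)?", .nameRe, .tokRe, .tokRe)

componentId <- function(molecule, component, occurrence) {
  sprintf("%s.%s#%d", molecule, component, as.integer(occurrence))
}

stateId <- function(molecule, component, occurrence, state) {
  sprintf("%s.%s#%d~%s", molecule, component, as.integer(occurrence), state)
}

endpointId <- function(molecule, component, occurrence, state = NA_character_) {
  base <- componentId(molecule, component, occurrence)
  if (is.na(state)) base else paste0(base, "~", state)
}

edgeId <- function(endpoint1, endpoint2) {
  ep <- sort(c(endpoint1, endpoint2), method = "radix")
  paste0("{", ep[1L], "|", ep[2L], "}")
}

unstructuredId <- function(molecule, kind = c("syn", "deg")) {
  kind <- match.arg(kind)
  paste0(molecule, ".@", kind)
}

#' Classify or validate a canonical element identifier
#'
#' Checks an identifier string against the element identifier grammar
#' (molecule \code{M}, component \code{M.c#k}, state \code{M.c#k~s}, edge
#' \code{\{M.c#k[~s]|N.d#j[~t]\}} with endpoints sorted, unstructured
#' \code{M.@syn} / \code{M.@deg}) and returns its kind.
#'
#' @param id Character scalar identifier.
#' @return One of \code{"molecule"}, \code{"component"}, \code{"state"},
#'   \code{"edge"}, \code{"unstructured"}; an error for a malformed
#'   identifier.
#' @examples
#' elementKind("egfr")
#' elementKind("Shc.Y317#1~pY")
#' elementKind("{Grb2.SH3#1|Sos.dom#1}")
#' @export
elementKind <- function(id) {
  stopifnot(is.character(id), length(id) == 1L, !is.na(id))
  full <- function(re) grepl(paste0("^", re, "$"), id)
  if (full(.nameRe)) return("molecule")
  if (full(sprintf("%s\\.%s#[0-9]+", .nameRe, .tokRe))) return("component")
  if (full(sprintf("%s\\.%s#[0-9]+~%s", .nameRe, .tokRe, .tokRe))) return("state")
  if (full(sprintf("%s\\.@(syn|deg)", .nameRe))) return("unstructured")
  if (full(sprintf("\\{(%s)\\|(%s)\\}", .endpointRe, .endpointRe))) {
    ep <- strsplit(substr(id, 2L, nchar(id) - 1L), "|", fixed = TRUE)[[1L]]
    if (!identical(ep, sort(ep, method = "radix")))
      stop(sprintf("malformed element id '%s': edge endpoints must be sorted lexicographically", id),
           call. = FALSE)
    return("edge")
  }
  stop(sprintf(
    paste0("malformed element id '%s'; expected molecule 'M', component 'M.c#k', ",
           "state 'M.c#k~s', edge '{M.c#k[~s]|N.d#j[~t]}' (endpoints sorted), ",
           "or unstructured 'M.@syn'/'M.@deg'"), id), call. = FALSE)
}

# molecule owning an element (first name token of the id)
elementMolecule <- function(id) {
  sub(sprintf("^\\{?(%s).*$", .nameRe), "\\1", id)
}
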