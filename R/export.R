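#' Export a contact map to a standard graph format
#'
#' Serializes a contact map to GraphML, DOT or a documented JSON dialect.
#' Nodes carry kind / molecule / component / occurrence / state / modifiable
#' attributes; molecule containment is encoded as a \code{parent} attribute
#' (GraphML, JSON) or a cluster subgraph (DOT). Output ordering is
#' deterministic, so identical maps give byte-identical documents.
#'
#' The JSON dialect is lossless for contact-map structure: an object with
#' \code{model}, \code{molecules} (each with \code{name} and
#' \code{components}: name, occurrence, states, modifiable, binds),
#' \code{edges} (end1, end2, rules) and \code{unstructured} (kind, molecule);
#' [contactMapFromJSON()] reconstructs an identical map from it.
#'
#' @param cmap A [ContactMap-class].
#' @param format One of \code{"graphml"}, \code{"dot"}, \code{"json"}.
#' @param path Optional output file.
#' @return The document text (invisibly when \code{path} is given).
#' @export
exportGraph <- function(cmap, format = c("json", "graphml", "dot"), path = NULL) {
  stopifnot(methods::is(cmap, "ContactMap"))
  if (!is.character(format) || !format[1L] %in% c("json", "graphml", "dot"))
    stop(sprintf("unknown format '%s'; supported formats: graphml, dot, json",
                 format[1L]))
  format <- match.arg(format)
  text <- switch(format,
                 json = .exportJSON(cmap),
                 graphml = .exportGraphML(cmap),
                 dot = .exportDOT(cmap))
  if (!is.null(path)) {
    writeLines(sub("\n$", "", text), path)
    return(invisible(text))
  }
  text
}

.nodeTable <- function(cmap) {
  rows <- list()
  add <- function(...) rows[[length(rows) + 1L]] <<- data.frame(
    ..., stringsAsFactors = FALSE)
  for (m in cmap@molecules) {
    add(id = m$name, kind = "molecule", molecule = m$name,
        component = NA_character_, occurrence = NA_integer_,
        state = NA_character_, modifiable = NA, parent = NA_character_)
    for (cc in m$components) {
      cid <- componentId(m$name, cc$name, cc$occurrence)
      add(id = cid, kind = "component", molecule = m$name,
          component = cc$name, occurrence = cc$occurrence,
          state = NA_character_, modifiable = cc$modifiable, parent = m$name)
      for (s in cc$states)
        add(id = paste0(cid, "~", s), kind = "state", molecule = m$name,
            component = cc$name, occurrence = cc$occurrence, state = s,
            modifiable = NA, parent = cid)
    }
  }
  if (nrow(cmap@unstructured))
    for (k in seq_len(nrow(cmap@unstructured)))
      add(id = cmap@unstructured$id[k], kind = "unstructured",
          molecule = cmap@unstructured$molecule[k], component = NA_character_,
          occurrence = NA_integer_, state = NA_character_, modifiable = NA,
          parent = cmap@unstructured$molecule[k])
  if (!length(rows))
    return(data.frame(id = character(), kind = character(),
                      molecule = character(), component = character(),
                      occurrence = integer(), state = character(),
                      modifiable = logical(), parent = character()))
  do.call(rbind, rows)
}

.xmlEscape <- function(s) {
  s <- gsub("&", "&amp;", s, fixed = TRUE)
  s <- gsub("<", "&lt;", s, fixed = TRUE)
  s <- gsub(">", "&gt;", s, fixed = TRUE)
  gsub("\"", "&quot;", s, fixed = TRUE)
}

.exportGraphML <- function(cmap) {
  nodes <- .nodeTable(cmap)
  keys <- c(kind = "string", molecule = "string", component = "string",
            occurrence = "int", state = "string", modifiable = "boolean",
            parent = "string")
  out <- c('<?xml version="1.0" encoding="UTF-8"?>',
           '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
           sprintf('  <key id="%s" for="node" attr.name="%s" attr.type="%s"/>',
                   names(keys), names(keys), keys),
           '  <key id="rules" for="edge" attr.name="rules" attr.type="string"/>',
           sprintf('  <graph id="%s" edgedefault="undirected">',
                   .xmlEscape(cmap@modelName)))
  for (k in seq_len(nrow(nodes))) {
    data <- character()
    for (a in names(keys)) {
      v <- nodes[[a]][k]
      if (is.na(v)) next
      if (is.logical(v)) v <- tolower(as.character(v))
      data <- c(data, sprintf('      <data key="%s">%s</data>', a,
                              .xmlEscape(as.character(v))))
    }
    out <- c(out, sprintf('    <node id="%s">', .xmlEscape(nodes$id[k])),
             data, '    </node>')
  }
  for (k in seq_len(nrow(cmap@edges))) {
    e1 <- sub("~[A-Za-z0-9_]+$", "", cmap@edges$end1[k])
    e2 <- sub("~[A-Za-z0-9_]+$", "", cmap@edges$end2[k])
    out <- c(out,
             sprintf('    <edge id="%s" source="%s" target="%s">',
                     .xmlEscape(cmap@edges$id[k]), .xmlEscape(e1), .xmlEscape(e2)),
             sprintf('      <data key="rules">%s</data>',
                     .xmlEscape(paste(sort(cmap@edges$rules[[k]]), collapse = ";"))),
             '    </edge>')
  }
  paste0(paste(c(out, '  </graph>', '</graphml>'), collapse = "\n"), "\n")
}

.dotQuote <- function(s) paste0('"', gsub('"', '\\"', s, fixed = TRUE), '"')

.exportDOT <- function(cmap) {
  out <- c(sprintf("graph %s {", .dotQuote(cmap@modelName)),
           "  node [shape=box];")
  for (mi in seq_along(cmap@molecules)) {
    m <- cmap@molecules[[mi]]
    out <- c(out, sprintf("  subgraph cluster_%d {", mi - 1L),
             sprintf("    label=%s;", .dotQuote(m$name)))
    for (cc in m$components) {
      cid <- componentId(m$name, cc$name, cc$occurrence)
      out <- c(out, sprintf("    %s [kind=component, modifiable=%s];",
                            .dotQuote(cid), tolower(as.character(cc$modifiable))))
      for (s in cc$states) {
        sid <- paste0(cid, "~", s)
        out <- c(out, sprintf("    %s [kind=state];", .dotQuote(sid)),
                 sprintf("    %s -- %s [style=dotted];",
                         .dotQuote(cid), .dotQuote(sid)))
      }
    }
    out <- c(out, "  }")
  }
  if (nrow(cmap@unstructured))
    for (k in seq_len(nrow(cmap@unstructured)))
      out <- c(out, sprintf("  %s [kind=unstructured, shape=circle];",
                            .dotQuote(cmap@unstructured$id[k])))
  for (k in seq_len(nrow(cmap@edges)))
    out <- c(out, sprintf("  %s -- %s;",
                          .dotQuote(sub("~[A-Za-z0-9_]+$", "", cmap@edges$end1[k])),
                          .dotQuote(sub("~[A-Za-z0-9_]+$", "", cmap@edges$end2[k]))))
  paste0(paste(c(out, "}"), collapse = "\n"), "\n")
}

.exportJSON <- function(cmap) {
  obj <- list(
    dialect = "cmapkit-contact-map-v1",
    model = cmap@modelName,
    molecules = lapply(cmap@molecules, function(m) list(
      name = m$name,
      components = lapply(m$components, function(cc) list(
        name = cc$name, occurrence = cc$occurrence,
        states = as.list(cc$states),
        modifiable = cc$modifiable, binds = cc$binds)))),
    edges = if (nrow(cmap@edges)) lapply(seq_len(nrow(cmap@edges)), function(k)
      list(end1 = cmap@edges$end1[k], end2 = cmap@edges$end2[k],
           rules = as.list(sort(cmap@edges$rules[[k]])))) else list(),
    unstructured = if (nrow(cmap@unstructured))
      lapply(seq_len(nrow(cmap@unstructured)), function(k)
        list(kind = cmap@unstructured$kind[k],
             molecule = cmap@unstructured$molecule[k])) else list())
  paste0(jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE, digits = NA),
         "\n")
}

#' Reconstruct a contact map from its JSON export
#'
#' Inverse of \code{exportGraph(cmap, "json")}: rebuilds a
#' [ContactMap-class] with identical element identifiers.
#'
#' @param text JSON text (or lines).
#' @param path Optional file to read instead of \code{text}.
#' @return A [ContactMap-class].
#' @export
contactMapFromJSON <- function(text = NULL, path = NULL) {
  if (!is.null(path)) text <- paste(readLines(path, warn = FALSE), collapse = "\n")
  obj <- jsonlite::fromJSON(text, simplifyVector = FALSE)
  if (!identical(obj$dialect, "cmapkit-contact-map-v1"))
    stop("not a cmapkit contact-map JSON document")
  molecules <- lapply(obj$molecules, function(m) list(
    name = m$name,
    components = lapply(m$components, function(cc) list(
      name = cc$name, occurrence = as.integer(cc$occurrence),
      states = as.character(unlist(cc$states)),
      modifiable = isTRUE(cc$modifiable), binds = isTRUE(cc$binds)))))
  nE <- length(obj$edges)
  edges <- data.frame(
    id = vapply(obj$edges, function(e) edgeId(e$end1, e$end2), character(1)),
    end1 = vapply(obj$edges, `[[`, "", "end1"),
    end2 = vapply(obj$edges, `[[`, "", "end2"),
    stringsAsFactors = FALSE, row.names = NULL)
  edges$rules <- lapply(obj$edges, function(e) as.character(unlist(e$rules)))
  if (nE) edges <- edges[order(edges$id, method = "radix"), , drop = FALSE]
  uns <- data.frame(
    id = vapply(obj$unstructured, function(u)
      unstructuredId(u$molecule, u$kind), character(1)),
    kind = vapply(obj$unstructured, `[[`, "", "kind"),
    molecule = vapply(obj$unstructured, `[[`, "", "molecule"),
    stringsAsFactors = FALSE, row.names = NULL)
  if (nrow(uns)) uns <- uns[order(uns$id, method = "radix"), , drop = FALSE]
  methods::new("ContactMap", modelName = obj$model, molecules = molecules,
               edges = edges, unstructured = uns)
}
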