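#' Read and write stored layout position files
#'
#' The native position-file dialect is a header line
#' \code{#cmapkit-layout v1} followed by one tab-separated line
#' \code{ElementId<TAB>x<TAB>y} per element (abstract layout units, y-down).
#' \code{readLayoutFile()} also accepts plain whitespace-delimited triples
#' \code{identifier x y} without a header. Unknown identifiers are retained
#' verbatim; resolution against a concrete contact map happens at layout
#' stabilization time. \code{writeLayoutFile()} emits the native dialect with
#' entries sorted by identifier, so output is bit-stable.
#'
#' @param text Character vector of lines or a single string (alternative to
#'   \code{path}).
#' @param path File to read from / write to.
#' @param name Layout name (defaults to the file stem, or \code{"layout"}).
#' @param layout A [StoredLayout-class] object.
#' @return \code{readLayoutFile()}: a [StoredLayout-class].
#'   \code{writeLayoutFile()}: the file text, invisibly when \code{path} is
#'   given.
#' @examples
#' sl <- readLayoutFile(text = "egfr 120.0 80.0")
#' positions(sl)
#' cat(writeLayoutFile(sl))
#' @export
readLayoutFile <- function(text = NULL, path = NULL, name = NULL) {
  if (!is.null(path)) {
    text <- readLines(path, warn = FALSE)
    if (is.null(name)) name <- tools::file_path_sans_ext(basename(path))
  }
  if (is.null(name)) name <- "layout"
  if (is.null(text)) stop("either 'text' or 'path' must be given")
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  version <- "v1"
  native <- length(lines) && grepl("^#cmapkit-layout[[:space:]]", lines[1L])
  if (native)
    version <- trimws(sub("^#cmapkit-layout", "", lines[1L]))
  ids <- character(); xs <- numeric(); ys <- numeric()
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (grepl("^[[:space:]]*(#|$)", ln)) next
    tok <- strsplit(trimws(ln), "[[:space:]]+")[[1L]]
    if (length(tok) != 3L)
      stop(sprintf("layout line %d: expected 'identifier x y', got '%s'", i, ln))
    x <- suppressWarnings(as.numeric(tok[2L]))
    y <- suppressWarnings(as.numeric(tok[3L]))
    if (is.na(x) || is.na(y))
      stop(sprintf("layout line %d: non-numeric coordinate in '%s'", i, ln))
    ids <- c(ids, tok[1L]); xs <- c(xs, x); ys <- c(ys, y)
  }
  methods::new("StoredLayout", name = name,
               positions = data.frame(id = ids, x = xs, y = ys,
                                      stringsAsFactors = FALSE),
               version = version)
}

#' @rdname readLayoutFile
#' @export
writeLayoutFile <- function(layout, path = NULL) {
  stopifnot(methods::is(layout, "StoredLayout"))
  p <- layout@positions
  p <- p[order(p$id, method = "radix"), , drop = FALSE]
  out <- c(paste0("#cmapkit-layout ", layout@version),
           sprintf("%s\t%.15g\t%.15g", p$id, p$x, p$y))
  text <- paste0(paste(out, collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(text))
  }
  text
}

#' Construct a stored layout from coordinates
#'
#' @param ids Character vector of element identifiers.
#' @param x,y Numeric coordinates (abstract units).
#' @param name Layout name.
#' @return A [StoredLayout-class].
#' @export
storedLayout <- function(ids = character(), x = numeric(), y = numeric(),
                         name = "layout") {
  methods::new("StoredLayout", name = name,
               positions = data.frame(id = as.character(ids), x = as.numeric(x),
                                      y = as.numeric(y), stringsAsFactors = FALSE),
               version = "v1")
}
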