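#' Highlight request for rendered panels
#'
#' @param ids Character vector of element identifiers to highlight.
#' @param style Overlay style: \code{"similarity"} (green) or
#'   \code{"difference"} (red-orange).
#' @param background Tint the panel background to mark the model as a member
#'   of a pairwise comparison even when \code{ids} is empty (the
#'   empty-overlay case of a complete-subgraph comparison)?
#' @return A \code{highlightSet} list, consumed by [renderPanels()].
#' @export
highlightSet <- function(ids = character(),
                         style = c("similarity", "difference"),
                         background = TRUE) {
  style <- match.arg(style)
  for (id in ids) elementKind(id)
  structure(list(ids = as.character(ids), style = style,
                 background = isTRUE(background)),
            class = "highlightSet")
}

.hlColors <- list(similarity = c(fill = "#3faa5f", bg = "#eef7ee"),
                  difference = c(fill = "#e05a2b", bg = "#fdf0e9"))

.fmt <- function(x) formatC(x, format = "f", digits = 2)

#' Render a family as grayscale small-multiple SVG panels
#'
#' Draws one panel per model, row-wise in the order given (typically from
#' [sortFamily()]): molecule boxes containing component and state
#' rectangles, binding edges between components (self-edges as loops),
#' dashed connections to unstructured synthesis/degradation nodes, all in
#' grayscale. Highlighted element sets are overlaid as one padded convex
#' hull per connected highlighted group, filled in the style color at 40%
#' opacity; panels belonging to a pairwise comparison get a tinted
#' background. Output is deterministic: identical inputs give byte-identical
#' SVG.
#'
#' @param family List of [ContactMap-class] objects.
#' @param layouts List of [CMapLayout-class], parallel to \code{family}
#'   (e.g. from [stabilizeLayouts()]).
#' @param ordering Optional [FamilyOrdering-class]; default is input order.
#' @param highlights Optional named list (by model name) of [highlightSet()]
#'   objects. Ids absent from a model are skipped with a warning.
#' @param panelWidth,panelHeight Panel size in SVG user units.
#' @param path Optional output file.
#' @return SVG text (invisibly when \code{path} is given).
#' @export
renderPanels <- function(family, layouts, ordering = NULL, highlights = NULL,
                         panelWidth = 340, panelHeight = 260, path = NULL) {
  stopifnot(length(family) == length(layouts))
  nms <- vapply(family, modelName, "")
  ord <- if (is.null(ordering)) seq_along(family) else ordering@ordering
  n <- length(ord)
  ncols <- max(1L, ceiling(sqrt(n)))
  nrows <- max(1L, ceiling(n / ncols))
  W <- ncols * panelWidth; H <- nrows * panelHeight
  out <- c(sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 %d %d">',
                   W, H, W, H),
           sprintf('<rect x="0" y="0" width="%d" height="%d" fill="#ffffff"/>', W, H))
  for (k in seq_along(ord)) {
    i <- ord[k]
    px <- ((k - 1L) %% ncols) * panelWidth
    py <- ((k - 1L) %/% ncols) * panelHeight
    hl <- if (!is.null(highlights)) highlights[[nms[i]]] else NULL
    out <- c(out, .renderPanel(family[[i]], layouts[[i]], hl,
                               px, py, panelWidth, panelHeight))
  }
  text <- paste0(paste(c(out, "</svg>"), collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(sub("\n$", "", text), path)
    return(invisible(text))
  }
  text
}

.renderPanel <- function(cmap, layout, hl, px, py, pw, ph) {
  nodes <- layout@nodes
  margin <- 18
  titleH <- 16
  # map abstract layout units into the panel content area (uniform scale)
  if (nrow(nodes)) {
    x0 <- min(nodes$x - nodes$w / 2); x1 <- max(nodes$x + nodes$w / 2)
    y0 <- min(nodes$y - nodes$h / 2); y1 <- max(nodes$y + nodes$h / 2)
    sc <- min((pw - 2 * margin) / max(x1 - x0, 1),
              (ph - 2 * margin - titleH) / max(y1 - y0, 1), 1)
    tx <- function(x) (x - (x0 + x1) / 2) * sc + pw / 2
    ty <- function(y) (y - (y0 + y1) / 2) * sc + (ph + titleH) / 2
  } else {
    sc <- 1; tx <- function(x) x + pw / 2; ty <- function(y) y + ph / 2
  }
  geo <- data.frame(id = nodes$id, kind = nodes$kind,
                    x = tx(nodes$x), y = ty(nodes$y),
                    w = nodes$w * sc, h = nodes$h * sc,
                    stringsAsFactors = FALSE)
  row.names(geo) <- geo$id

  bg <- "#ffffff"
  if (!is.null(hl) && (hl$background || length(hl$ids)))
    bg <- .hlColors[[hl$style]][["bg"]]
  out <- c(sprintf('<g transform="translate(%s,%s)" data-model="%s">',
                   .fmt(px), .fmt(py), cmap@modelName),
           sprintf('<rect x="0" y="0" width="%d" height="%d" fill="%s" stroke="#999999"/>',
                   pw, ph, bg),
           sprintf('<text x="%s" y="12" font-size="11" font-family="sans-serif" fill="#222222">%s</text>',
                   .fmt(6), .xmlEscape(cmap@modelName)))

  epGeo <- function(ep) {
    base <- sub("~[A-Za-z0-9_]+$", "", ep)
    if (ep %in% geo$id) geo[ep, ] else geo[base, ]
  }
  # edges first (under the boxes' components but over the molecule fill is
  # fine either way; draw before node rects so rects sit on top)
  for (k in seq_len(nrow(cmap@edges))) {
    g1 <- epGeo(cmap@edges$end1[k]); g2 <- epGeo(cmap@edges$end2[k])
    if (cmap@edges$end1[k] == cmap@edges$end2[k]) {
      r <- max(g1$w, 10)
      out <- c(out, sprintf('<circle cx="%s" cy="%s" r="%s" fill="none" stroke="#444444" stroke-width="1.2" data-edge="%s"/>',
                            .fmt(g1$x + g1$w / 2), .fmt(g1$y - g1$h / 2),
                            .fmt(r / 2), .xmlEscape(cmap@edges$id[k])))
    } else {
      out <- c(out, sprintf('<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="#444444" stroke-width="1.2" data-edge="%s"/>',
                            .fmt(g1$x), .fmt(g1$y), .fmt(g2$x), .fmt(g2$y),
                            .xmlEscape(cmap@edges$id[k])))
    }
  }
  for (k in seq_len(nrow(cmap@unstructured))) {
    uid <- cmap@unstructured$id[k]
    gu <- geo[uid, ]; gm <- geo[cmap@unstructured$molecule[k], ]
    out <- c(out, sprintf('<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="#777777" stroke-width="1" stroke-dasharray="3,2"/>',
                          .fmt(gu$x), .fmt(gu$y), .fmt(gm$x), .fmt(gm$y)))
  }
  rectFor <- function(g, fill, stroke, extra = "") {
    sprintf('<rect x="%s" y="%s" width="%s" height="%s" fill="%s" stroke="%s"%s data-id="%s"/>',
            .fmt(g$x - g$w / 2), .fmt(g$y - g$h / 2), .fmt(g$w), .fmt(g$h),
            fill, stroke, extra, .xmlEscape(g$id))
  }
  mods <- .modifiableIds(cmap)
  for (k in seq_len(nrow(geo))) {
    g <- geo[k, ]
    out <- c(out, switch(
      g$kind,
      molecule = rectFor(g, "#ececec", "#555555", ' rx="4"'),
      component = rectFor(g, if (g$id %in% mods) "#b9b9b9" else "#d6d6d6", "#444444"),
      state = rectFor(g, "#c9c9c9", "#666666"),
      unstructured = rectFor(g, "#f5f5f5", "#888888", ' rx="6"')))
    if (g$kind %in% c("molecule", "component")) {
      lab <- if (g$kind == "molecule") g$id else
        sub("^[^.]*\\.", "", g$id)
      out <- c(out, sprintf('<text x="%s" y="%s" font-size="%s" font-family="sans-serif" fill="#333333" text-anchor="middle">%s</text>',
                            .fmt(g$x),
                            .fmt(if (g$kind == "molecule") g$y - g$h / 2 + 10 * sc else g$y + 3),
                            .fmt(if (g$kind == "molecule") max(8, 10 * sc) else max(6, 8 * sc)),
                            .xmlEscape(lab)))
    }
  }
  if (!is.null(hl) && length(hl$ids))
    out <- c(out, .renderHulls(cmap, geo, hl))
  c(out, "</g>")
}

.modifiableIds <- function(cmap) {
  unlist(lapply(cmap@molecules, function(m)
    vapply(Filter(function(cc) isTRUE(cc$modifiable), m$components),
           function(cc) componentId(m$name, cc$name, cc$occurrence), "")))
}

# one padded convex hull per connected highlighted group (a bubbleset
# approximation); the hull is the convex hull of every group glyph's
# pad-inflated rectangle corners, so each highlighted glyph lies inside it
.renderHulls <- function(cmap, geo, hl, pad = 7) {
  ids <- unique(hl$ids)
  present <- ids %in% c(geo$id, cmap@edges$id)
  if (any(!present)) {
    warning(sprintf("model '%s': %d highlight id(s) not in the model skipped",
                    cmap@modelName, sum(!present)), call. = FALSE)
    ids <- ids[present]
  }
  if (!length(ids)) return(character())
  ids <- sort(ids, method = "radix")

  links <- matrix(character(), 0L, 2L)
  addLink <- function(a, b) {
    if (a %in% ids && b %in% ids) links <<- rbind(links, c(a, b))
  }
  for (k in seq_len(nrow(cmap@edges))) {
    eid <- cmap@edges$id[k]
    for (ep in c(cmap@edges$end1[k], cmap@edges$end2[k])) {
      addLink(eid, ep)
      addLink(eid, sub("~[A-Za-z0-9_]+$", "", ep))
    }
  }
  for (m in cmap@molecules) {
    for (cc in m$components) {
      cid <- componentId(m$name, cc$name, cc$occurrence)
      addLink(m$name, cid)
      for (s in cc$states) addLink(cid, paste0(cid, "~", s))
    }
  }
  for (k in seq_len(nrow(cmap@unstructured)))
    addLink(cmap@unstructured$id[k], cmap@unstructured$molecule[k])

  gr <- igraph::graph_from_data_frame(
    if (nrow(links)) data.frame(from = links[, 1L], to = links[, 2L])
    else data.frame(from = character(), to = character()),
    directed = FALSE, vertices = data.frame(name = ids))
  comp <- igraph::components(gr)$membership

  glyphPoints <- function(id) {
    if (elementKind(id) == "edge") {
      ep <- strsplit(substr(id, 2L, nchar(id) - 1L), "|", fixed = TRUE)[[1L]]
      do.call(rbind, lapply(ep, function(e) {
        base <- sub("~[A-Za-z0-9_]+$", "", e)
        g <- if (e %in% geo$id) geo[e, ] else geo[base, ]
        .rectCorners(g, pad)
      }))
    } else {
      .rectCorners(geo[id, ], pad)
    }
  }
  out <- character()
  col <- .hlColors[[hl$style]][["fill"]]
  for (grp in sort(unique(comp))) {
    members <- sort(names(comp)[comp == grp], method = "radix")
    pts <- do.call(rbind, lapply(members, glyphPoints))
    hull <- grDevices::chull(pts[, 1L], pts[, 2L])
    hp <- pts[hull, , drop = FALSE]
    out <- c(out, sprintf('<polygon class="highlight-hull" points="%s" fill="%s" fill-opacity="0.4" stroke="%s" stroke-opacity="0.6" data-ids="%s"/>',
                          paste(sprintf("%s,%s", .fmt(hp[, 1L]), .fmt(hp[, 2L])),
                                collapse = " "),
                          col, col, .xmlEscape(paste(members, collapse = " "))))
  }
  out
}

.rectCorners <- function(g, pad = 0) {
  x0 <- g$x - g$w / 2 - pad; x1 <- g$x + g$w / 2 + pad
  y0 <- g$y - g$h / 2 - pad; y1 <- g$y + g$h / 2 + pad
  cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1))
}
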