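# Geometry constants (abstract layout units, y-down). Components are laid on
# a grid inside their molecule box; states stack in a column right of their
# component cell.
.geom <- list(compW = 32, compH = 14, stateW = 24, stateH = 10,
              cellPadX = 6, cellPadY = 5, boxPad = 8, titleH = 14,
              unstrW = 20, unstrH = 12)

.stableHash <- function(s) {
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

seedForModel <- function(name, seed) {
  bitwXor(.stableHash(name), as.integer(seed) %% 2147483647L)
}

.moleculeBoxDims <- function(mol) {
  g <- .geom
  n <- length(mol$components)
  ncol <- ceiling(sqrt(n))
  nrow <- ceiling(n / ncol)
  hasStates <- vapply(mol$components, function(cc) length(cc$states) > 0L, NA)
  maxStates <- vapply(mol$components, function(cc) length(cc$states), 0L)
  cellW <- g$compW + 2 * g$cellPadX + ifelse(hasStates, g$stateW + 4, 0)
  cellH <- pmax(g$compH, maxStates * (g$stateH + 2)) + 2 * g$cellPadY
  colW <- vapply(seq_len(ncol), function(j) {
    ix <- seq(j, n, by = ncol)
    max(cellW[ix])
  }, 0)
  rowH <- vapply(seq_len(nrow), function(i) {
    ix <- seq((i - 1) * ncol + 1, min(i * ncol, n))
    max(cellH[ix])
  }, 0)
  list(ncol = ncol, nrow = nrow, colW = colW, rowH = rowH,
       w = sum(colW) + 2 * g$boxPad,
       h = sum(rowH) + 2 * g$boxPad + g$titleH)
}

#' Deterministic force-directed layout of one contact map
#'
#' Two-level layout: molecule boxes are placed by a Fruchterman-Reingold
#' force-directed pass over the molecule-adjacency graph (molecules adjacent
#' iff a contact-map edge joins their components; fixed iteration count,
#' fixed cooling), components on a grid inside their molecule box in
#' declaration order, states stacked beside their component, and
#' unstructured nodes attached outside their molecule's box. Molecules and
#' components named in \code{pinned} keep their input coordinates exactly;
#' the seed fixes all remaining randomness, so identical inputs give a
#' bit-identical layout. A single unpinned molecule is placed at the origin.
#'
#' @param cmap A [ContactMap-class].
#' @param seed Integer seed for the force-directed pass.
#' @param pinned Optional [StoredLayout-class] of molecule/component
#'   positions to pin; entries naming elements absent from the map are
#'   ignored with a warning.
#' @param iterations Iterations of the force-directed pass (default 300).
#' @return A [CMapLayout-class].
#' @seealso [stabilizeLayouts()], [renderPanels()]
#' @export
forceLayout <- function(cmap, seed = 0L, pinned = NULL, iterations = 300L) {
  stopifnot(methods::is(cmap, "ContactMap"))
  g <- .geom
  molNames <- vapply(cmap@molecules, `[[`, "", "name")
  compIds <- unlist(lapply(cmap@molecules, function(m)
    vapply(m$components, function(cc) componentId(m$name, cc$name, cc$occurrence), "")))
  pins <- data.frame(id = character(), x = numeric(), y = numeric())
  if (!is.null(pinned) && nrow(pinned@positions)) {
    pins <- pinned@positions
    known <- pins$id %in% c(molNames, compIds)
    if (any(!known))
      warning(sprintf("model '%s': %d pinned entr%s not in the contact map ignored",
                      cmap@modelName, sum(!known), if (sum(!known) == 1L) "y" else "ies"),
              call. = FALSE)
    pins <- pins[known, , drop = FALSE]
  }

  dims <- lapply(cmap@molecules, .moleculeBoxDims)
  centers <- .placeMolecules(cmap, molNames, pins, dims, seed, iterations)

  rows <- list()
  addNode <- function(id, kind, molecule, x, y, w, h, pin) {
    rows[[length(rows) + 1L]] <<- data.frame(
      id = id, kind = kind, molecule = molecule, x = x, y = y, w = w, h = h,
      pinned = pin, stringsAsFactors = FALSE)
  }

  pinnedIds <- pins$id
  pinXY <- function(id) {
    k <- match(id, pins$id)
    c(pins$x[k], pins$y[k])
  }

  for (mi in seq_along(cmap@molecules)) {
    mol <- cmap@molecules[[mi]]
    d <- dims[[mi]]
    cx <- centers[mi, 1L]; cy <- centers[mi, 2L]
    addNode(mol$name, "molecule", mol$name, cx, cy, d$w, d$h,
            mol$name %in% pinnedIds)
    left <- cx - d$w / 2 + g$boxPad
    top <- cy - d$h / 2 + g$titleH + g$boxPad
    for (ci in seq_along(mol$components)) {
      cc <- mol$components[[ci]]
      cid <- componentId(mol$name, cc$name, cc$occurrence)
      col <- (ci - 1L) %% d$ncol + 1L
      row <- (ci - 1L) %/% d$ncol + 1L
      cellX <- left + sum(d$colW[seq_len(col - 1L)])
      cellY <- top + sum(d$rowH[seq_len(row - 1L)])
      if (cid %in% pinnedIds) {
        xy <- pinXY(cid)
        compX <- xy[1L]; compY <- xy[2L]
        compPinned <- TRUE
      } else {
        compX <- cellX + g$cellPadX + g$compW / 2
        compY <- cellY + d$rowH[row] / 2
        compPinned <- FALSE
      }
      addNode(cid, "component", mol$name, compX, compY, g$compW, g$compH,
              compPinned)
      if (length(cc$states)) {
        sx <- compX + g$compW / 2 + 4 + g$stateW / 2
        sy0 <- compY - (length(cc$states) - 1L) * (g$stateH + 2) / 2
        for (si in seq_along(cc$states)) {
          addNode(paste0(cid, "~", cc$states[si]), "state", mol$name,
                  sx, sy0 + (si - 1L) * (g$stateH + 2), g$stateW, g$stateH,
                  FALSE)
        }
      }
    }
  }
  if (nrow(cmap@unstructured)) {
    for (k in order(cmap@unstructured$id, method = "radix")) {
      mn <- cmap@unstructured$molecule[k]
      mi <- match(mn, molNames)
      d <- dims[[mi]]
      off <- if (cmap@unstructured$kind[k] == "syn") -1 else 1
      addNode(cmap@unstructured$id[k], "unstructured", mn,
              centers[mi, 1L] + off * (d$w / 2 + 16),
              centers[mi, 2L] - d$h / 2 - 10,
              g$unstrW, g$unstrH, FALSE)
    }
  }
  nodes <- do.call(rbind, rows)
  if (is.null(nodes))
    nodes <- data.frame(id = character(), kind = character(),
                        molecule = character(), x = numeric(), y = numeric(),
                        w = numeric(), h = numeric(), pinned = logical())
  methods::new("CMapLayout", modelName = cmap@modelName, nodes = nodes)
}

# molecule centers: pinned exact, rest Fruchterman-Reingold over the
# molecule-adjacency graph
.placeMolecules <- function(cmap, molNames, pins, dims, seed, iterations) {
  n <- length(molNames)
  if (n == 0L) return(matrix(numeric(), 0L, 2L))
  pinIdx <- match(molNames, pins$id)
  isPinned <- !is.na(pinIdx)
  centers <- matrix(0, n, 2L)
  centers[isPinned, 1L] <- pins$x[pinIdx[isPinned]]
  centers[isPinned, 2L] <- pins$y[pinIdx[isPinned]]
  if (all(isPinned)) return(centers)
  if (n == 1L) return(centers)  # single unpinned molecule at the origin

  ends <- cbind(elementMolecule(cmap@edges$end1), elementMolecule(cmap@edges$end2))
  ends <- ends[ends[, 1L] != ends[, 2L], , drop = FALSE]
  gr <- igraph::graph_from_data_frame(
    data.frame(from = ends[, 1L], to = ends[, 2L]),
    directed = FALSE,
    vertices = data.frame(name = molNames))
  gr <- igraph::simplify(gr)

  boxDiag <- max(vapply(dims, function(d) sqrt(d$w^2 + d$h^2), 0))
  spacing <- boxDiag + 30
  set.seed(seed %% 2147483647L)
  start <- matrix(stats::runif(2L * n, -1, 1), n, 2L)
  anyPin <- any(isPinned)
  if (anyPin) {
    ctr <- colMeans(centers[isPinned, , drop = FALSE])
    spread <- max(spacing, max(abs(sweep(centers[isPinned, , drop = FALSE], 2L, ctr))) * 2)
    start <- sweep(start * spread / 2, 2L, ctr, `+`)
    start[isPinned, ] <- centers[isPinned, , drop = FALSE]
    inf <- rep(Inf, n)
    co <- igraph::layout_with_fr(
      gr, coords = start, niter = as.integer(iterations),
      minx = ifelse(isPinned, centers[, 1L], -inf),
      maxx = ifelse(isPinned, centers[, 1L], inf),
      miny = ifelse(isPinned, centers[, 2L], -inf),
      maxy = ifelse(isPinned, centers[, 2L], inf))
    co[isPinned, ] <- centers[isPinned, , drop = FALSE]
    return(co)
  }
  co <- igraph::layout_with_fr(gr, coords = start,
                               niter = as.integer(iterations))
  # normalize: center at origin, scale min pairwise distance to the box
  # spacing so boxes do not collapse onto each other
  co <- sweep(co, 2L, colMeans(co))
  if (n >= 2L) {
    dmin <- min(stats::dist(co))
    if (dmin < 1e-9) dmin <- 1e-9
    co <- co * (spacing / dmin)
  }
  co
}

#' Stabilize layouts across a model family
#'
#' Applies a stored reference layout across a family: in every model, each
#' element named in the reference and present in that model is pinned to the
#' reference coordinates, and the remaining elements are placed by
#' [forceLayout()] with a seed derived from the model name (stable hash XOR
#' the user seed). Shared elements therefore occupy identical positions in
#' every panel, so visual differences between panels reflect model
#' differences.
#'
#' @param family List of [ContactMap-class] objects.
#' @param reference A [StoredLayout-class] (element identifier grammar).
#' @param seed Integer user seed.
#' @return List of [CMapLayout-class], one per model, in family order.
#' @export
stabilizeLayouts <- function(family, reference, seed = 0L) {
  lapply(family, function(cm) {
    keep <- reference@positions$id %in% c(
      vapply(cm@molecules, `[[`, "", "name"),
      unlist(lapply(cm@molecules, function(m)
        vapply(m$components, function(cc)
          componentId(m$name, cc$name, cc$occurrence), ""))))
    ref <- methods::new("StoredLayout", name = reference@name,
                        positions = reference@positions[keep, , drop = FALSE],
                        version = reference@version)
    forceLayout(cm, seed = seedForModel(modelName(cm), seed), pinned = ref)
  })
}

#' Extract a stored layout from a concrete layout
#'
#' Keeps the molecule and component positions (the elements a stored layout
#' may pin) of a [CMapLayout-class], e.g. to persist a computed layout with
#' [writeLayoutFile()] or to reuse one model's layout as the reference for
#' [stabilizeLayouts()].
#'
#' @param layout A [CMapLayout-class].
#' @return A [StoredLayout-class].
#' @export
asStoredLayout <- function(layout) {
  stopifnot(methods::is(layout, "CMapLayout"))
  n <- layout@nodes
  n <- n[n$kind %in% c("molecule", "component"), , drop = FALSE]
  storedLayout(n$id, n$x, n$y, name = layout@modelName)
}
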