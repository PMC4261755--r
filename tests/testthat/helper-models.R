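# Shared fixtures and oracles, all built in code.

bnglText <- function(...) paste(c(...), collapse = "\n")

# minimal two-molecule binding model
toyBindModel <- function(name = "toy") {
  parseBNGL(bnglText(
    "begin molecule types",
    " A(x)",
    " B(y)",
    "end molecule types",
    "begin reaction rules",
    " A(x) + B(y) <-> A(x!1).B(y!1) kp, km",
    "end reaction rules"), name = name)
}

extdataDir <- function(family) {
  d <- system.file("extdata", family, package = "cmapkit")
  stopifnot(nzchar(d))
  d
}

loadFixtureMaps <- function(family) {
  models <- readBNGLDir(extdataDir(family))
  suppressWarnings(lapply(models, contactMap))
}

# independent O(n^2) oracle: enumerate all id pairs, count string equality
bruteSharedElements <- function(a, b) {
  ia <- elementIds(a); ib <- elementIds(b)
  out <- character()
  for (x in ia) for (y in ib) if (identical(x, y)) out <- c(out, x)
  sort(unique(out), method = "radix")
}

bruteOnly <- function(a, b) {
  ia <- elementIds(a); ib <- elementIds(b)
  out <- character()
  for (x in ia) {
    hit <- FALSE
    for (y in ib) if (identical(x, y)) hit <- TRUE
    if (!hit) out <- c(out, x)
  }
  sort(out, method = "radix")
}

# ray-casting point-in-polygon (boundary-inclusive within eps)
pointInPolygon <- function(px, py, vx, vy, eps = 1e-6) {
  n <- length(vx)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    # on-edge check
    dx <- vx[i] - vx[j]; dy <- vy[i] - vy[j]
    t <- if (abs(dx) + abs(dy) < eps) 0 else
      ((px - vx[j]) * dx + (py - vy[j]) * dy) / (dx^2 + dy^2)
    t <- min(max(t, 0), 1)
    if ((px - (vx[j] + t * dx))^2 + (py - (vy[j] + t * dy))^2 < eps)
      return(TRUE)
    if ((vy[i] > py) != (vy[j] > py) &&
        px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
      inside <- !inside
    j <- i
  }
  inside
}

# parse a rendered SVG and check every highlighted glyph lies inside its hull
checkHullContainment <- function(svgText) {
  skip_if_not_installed("xml2")
  doc <- xml2::read_xml(svgText)
  panels <- xml2::xml_find_all(doc, ".//*[local-name()='g']")
  ok <- TRUE
  nHulls <- 0L
  for (panel in panels) {
    hulls <- xml2::xml_find_all(panel, ".//*[local-name()='polygon'][@class='highlight-hull']")
    if (!length(hulls)) next
    rects <- xml2::xml_find_all(panel, ".//*[local-name()='rect'][@data-id]")
    rid <- xml2::xml_attr(rects, "data-id")
    for (h in hulls) {
      nHulls <- nHulls + 1L
      pts <- do.call(rbind, lapply(
        strsplit(strsplit(xml2::xml_attr(h, "points"), " ")[[1]], ","),
        as.numeric))
      members <- strsplit(xml2::xml_attr(h, "data-ids"), " ", fixed = TRUE)[[1]]
      glyphs <- setdiff(members, members[grepl("^\\{", members)])
      for (g in glyphs) {
        k <- match(g, rid)
        if (is.na(k)) next
        r <- rects[[k]]
        x <- as.numeric(xml2::xml_attr(r, "x")); y <- as.numeric(xml2::xml_attr(r, "y"))
        w <- as.numeric(xml2::xml_attr(r, "width")); hh <- as.numeric(xml2::xml_attr(r, "height"))
        for (cx in c(x, x + w)) for (cy in c(y, y + hh))
          if (!pointInPolygon(cx, cy, pts[, 1], pts[, 2])) ok <- FALSE
      }
    }
  }
  list(ok = ok, nHulls = nHulls)
}
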