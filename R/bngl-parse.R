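#' Parse BioNetGen language (BNGL) text into a Model
#'
#' Parses a practical subset of BNGL: \code{begin X} / \code{end X} blocks
#' with X in \{parameters, molecule types, species / seed species,
#' observables, functions, reaction rules\}, an optional \code{begin model} /
#' \code{end model} wrapper, \code{#} comments and backslash line
#' continuations. Parameters and functions are tolerated but skipped;
#' actions such as \code{generate_network} or \code{simulate} are ignored.
#' Rates are carried as opaque strings and never evaluated; compartments,
#' local rate functions and energy patterns are outside the subset.
#'
#' Molecules used in rules but absent from the \code{molecule types} block
#' are auto-declared from their maximal observed component signature, with
#' duplicate same-named components resolved by left-to-right position. A
#' component state used in a rule but missing from the declaration is
#' appended to the declaration with a warning. Reversible rules
#' (\code{<->}) are kept as single rules carrying two rate expressions.
#'
#' @param text BNGL source, either a single string or a character vector of
#'   lines.
#' @param name Model name; by default the file stem of \code{path} or
#'   \code{"model"}.
#' @param path Optional path to a \code{.bngl} file (used instead of
#'   \code{text}).
#' @return A [Model-class] object.
#' @examples
#' m <- parseBNGL(c(
#'   "begin molecule types",
#'   " egf(r)",
#'   " egfr(l)",
#'   "end molecule types",
#'   "begin reaction rules",
#'   " egf(r) + egfr(l) <-> egf(r!1).egfr(l!1) kp1, km1",
#'   "end reaction rules"), name = "toy")
#' length(rules(m))
#' @export
parseBNGL <- function(text = NULL, name = NULL, path = NULL) {
  if (!is.null(path)) {
    text <- readLines(path, warn = FALSE)
    if (is.null(name)) name <- tools::file_path_sans_ext(basename(path))
  }
  if (is.null(name)) name <- "model"
  if (is.null(text)) stop("either 'text' or 'path' must be given")
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  lines <- .joinContinuations(.stripComments(lines))
  blocks <- .splitBlocks(lines)

  moleculeTypes <- list()
  for (ln in blocks[["molecule types"]]) {
    mt <- .parseMoleculeTypeLine(ln)
    moleculeTypes[[mt$name]] <- mt
  }

  ruleList <- list()
  for (i in seq_along(blocks[["reaction rules"]])) {
    ruleList[[length(ruleList) + 1L]] <-
      .parseRuleLine(blocks[["reaction rules"]][i], index = length(ruleList) + 1L)
  }

  seeds <- character()
  for (ln in blocks[["seed species"]]) {
    tok <- strsplit(trimws(ln), "[[:space:]]+")[[1L]]
    tok <- .dropLeadingIndex(tok)
    if (length(tok)) seeds <- c(seeds, tok[1L])
  }

  obs <- data.frame(name = character(), pattern = character(),
                    stringsAsFactors = FALSE)
  for (ln in blocks[["observables"]]) {
    tok <- strsplit(trimws(ln), "[[:space:]]+")[[1L]]
    tok <- .dropLeadingIndex(tok)
    if (tolower(tok[1L]) %in% c("molecules", "species")) tok <- tok[-1L]
    if (length(tok) >= 2L)
      obs <- rbind(obs, data.frame(name = tok[1L],
                                   pattern = paste(tok[-1L], collapse = " "),
                                   stringsAsFactors = FALSE))
  }

  moleculeTypes <- .augmentDeclarations(moleculeTypes, ruleList)

  methods::new("Model",
               name = name,
               moleculeTypes = unname(moleculeTypes),
               rules = ruleList,
               seedSpecies = seeds,
               observables = obs,
               sourcePath = if (is.null(path)) "" else path)
}

#' Read all BNGL models in a directory
#'
#' Discovers \code{*.bngl} files (sorted lexicographically for reproducible
#' family ordering) and parses each with [parseBNGL()].
#'
#' @param dir Directory containing \code{.bngl} files.
#' @return Named list of [Model-class] objects.
#' @export
readBNGLDir <- function(dir) {
  if (!dir.exists(dir)) stop(sprintf("directory not found: %s", dir))
  files <- sort(list.files(dir, pattern = "\\.bngl$", full.names = TRUE))
  if (!length(files)) stop(sprintf("no .bngl files in %s", dir))
  models <- lapply(files, function(f) parseBNGL(path = f))
  names(models) <- vapply(models, modelName, "")
  models
}

## ---- internal lexing helpers -------------------------------------------

.stripComments <- function(lines) sub("#.*$", "", lines)

.joinContinuations <- function(lines) {
  out <- character()
  buf <- ""
  for (ln in lines) {
    if (grepl("\\\\[[:space:]]*$", ln)) {
      buf <- paste0(buf, sub("\\\\[[:space:]]*$", "", ln))
    } else {
      out <- c(out, paste0(buf, ln))
      buf <- ""
    }
  }
  if (nzchar(buf)) out <- c(out, buf)
  out
}

.knownBlocks <- c("parameters", "molecule types", "seed species", "species",
                  "observables", "functions", "reaction rules", "model")

.splitBlocks <- function(lines) {
  blocks <- list(`molecule types` = character(), `seed species` = character(),
                 observables = character(), `reaction rules` = character())
  current <- NULL
  for (ln in lines) {
    t <- trimws(ln)
    if (!nzchar(t)) next
    mBegin <- regmatches(t, regexec("^begin[[:space:]]+(.+)$", t))[[1L]]
    mEnd <- regmatches(t, regexec("^end[[:space:]]+(.+)$", t))[[1L]]
    if (length(mBegin)) {
      blk <- tolower(trimws(mBegin[2L]))
      if (blk == "species") blk <- "seed species"
      if (blk == "model") next
      if (!blk %in% .knownBlocks) {
        warning(sprintf("unknown block '%s' skipped", blk), call. = FALSE)
        current <- paste0(".skip:", blk)
      } else {
        current <- blk
      }
      next
    }
    if (length(mEnd)) {
      current <- NULL
      next
    }
    if (is.null(current)) next  # actions / stray text outside blocks
    if (startsWith(current, ".skip:") ||
        current %in% c("parameters", "functions")) next
    blocks[[current]] <- c(blocks[[current]], t)
  }
  blocks
}

.dropLeadingIndex <- function(tok) {
  if (length(tok) > 1L && grepl("^[0-9]+$", tok[1L])) tok[-1L] else tok
}

## ---- molecule type declarations ----------------------------------------

.parseMoleculeTypeLine <- function(line) {
  t <- trimws(line)
  t <- paste(.dropLeadingIndex(strsplit(t, "[[:space:]]+")[[1L]]), collapse = "")
  m <- regmatches(t, regexec(sprintf("^(%s)(\\((.*)\\))?$", .nameRe), t))[[1L]]
  if (!length(m)) stop(sprintf("cannot parse molecule type declaration '%s'", line))
  name <- m[2L]
  comps <- list()
  body <- if (length(m) >= 4L) m[4L] else ""
  if (nzchar(body)) {
    seen <- integer()
    for (cdecl in strsplit(body, ",", fixed = TRUE)[[1L]]) {
      parts <- strsplit(cdecl, "~", fixed = TRUE)[[1L]]
      cname <- parts[1L]
      if (!grepl(sprintf("^%s$", .tokRe), cname))
        stop(sprintf("bad component name '%s' in declaration '%s'", cname, line))
      occ <- (if (cname %in% names(seen)) seen[[cname]] else 0L) + 1L
      seen[[cname]] <- occ
      comps[[length(comps) + 1L]] <- list(name = cname, occurrence = occ,
                                          states = parts[-1L])
    }
  }
  if (!length(comps))
    comps <- list(list(name = name, occurrence = 1L, states = character()))
  list(name = name, components = comps)
}

## ---- pattern parsing ----------------------------------------------------

# split s on sep at paren depth 0; '+' preceded by '!' is a bond wildcard
.topSplit <- function(s, sep) {
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  depth <- 0L
  cut <- integer()
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch == "(") depth <- depth + 1L
    else if (ch == ")") depth <- depth - 1L
    else if (ch == sep && depth == 0L &&
             !(sep == "+" && i > 1L && chars[i - 1L] == "!"))
      cut <- c(cut, i)
  }
  if (!length(cut)) return(s)
  starts <- c(1L, cut + 1L)
  ends <- c(cut - 1L, length(chars))
  vapply(seq_along(starts), function(k)
    paste(chars[seq(starts[k], ends[k])], collapse = ""), "")
}

.parsePatternComponent <- function(s, context) {
  m <- regmatches(s, regexec(sprintf("^(%s)", .tokRe), s))[[1L]]
  if (!length(m)) stop(sprintf("bad component '%s' in %s", s, context))
  comp <- list(name = m[2L], state = NA_character_, bond = NA_character_)
  rest <- substr(s, nchar(m[2L]) + 1L, nchar(s))
  while (nzchar(rest)) {
    if (startsWith(rest, "~")) {
      ms <- regmatches(rest, regexec(sprintf("^~(%s)", .tokRe), rest))[[1L]]
      if (!length(ms)) stop(sprintf("bad state in component '%s' (%s)", s, context))
      comp$state <- ms[2L]
      rest <- substr(rest, nchar(ms[1L]) + 1L, nchar(rest))
    } else if (startsWith(rest, "!")) {
      mb <- regmatches(rest, regexec("^!(\\+|\\?|[0-9]+)", rest))[[1L]]
      if (!length(mb)) stop(sprintf("bad bond in component '%s' (%s)", s, context))
      comp$bond <- mb[2L]
      rest <- substr(rest, nchar(mb[1L]) + 1L, nchar(rest))
    } else {
      stop(sprintf("trailing '%s' in component '%s' (%s)", rest, s, context))
    }
  }
  comp
}

.parsePatternMolecule <- function(s, context) {
  m <- regmatches(s, regexec(sprintf("^(%s)(\\((.*)\\))?$", .nameRe), s))[[1L]]
  if (!length(m)) stop(sprintf("bad molecule pattern '%s' in %s", s, context))
  name <- m[2L]
  comps <- list()
  body <- if (length(m) >= 4L) m[4L] else ""
  if (nzchar(body)) {
    seen <- integer()
    for (cstr in .topSplit(body, ",")) {
      comp <- .parsePatternComponent(cstr, context)
      occ <- (if (comp$name %in% names(seen)) seen[[comp$name]] else 0L) + 1L
      seen[[comp$name]] <- occ
      comp$occurrence <- occ
      comps[[length(comps) + 1L]] <- comp
    }
  }
  list(name = name, components = comps)
}

# a side is "0" (empty) or complexes joined by +; a complex is molecules
# joined by .
.parsePatternSide <- function(s, context) {
  s <- gsub("[[:space:]]", "", s)
  if (s == "0" || s == "") return(list())
  lapply(.topSplit(s, "+"), function(cplx)
    lapply(.topSplit(cplx, "."), .parsePatternMolecule, context = context))
}

## ---- rules --------------------------------------------------------------

.parseRuleLine <- function(line, index) {
  t <- trimws(line)
  label <- NA_character_
  mLab <- regmatches(t, regexec(sprintf("^(%s):[[:space:]]*", .nameRe), t))[[1L]]
  if (length(mLab)) {
    label <- mLab[2L]
    t <- substr(t, nchar(mLab[1L]) + 1L, nchar(t))
  } else {
    tok <- strsplit(t, "[[:space:]]+")[[1L]]
    if (length(tok) > 1L && grepl("^[0-9]+$", tok[1L]))
      t <- paste(tok[-1L], collapse = " ")
  }
  reversible <- grepl("<->", t, fixed = TRUE)
  sides <- if (reversible) strsplit(t, "<->", fixed = TRUE)[[1L]]
           else strsplit(t, "->", fixed = TRUE)[[1L]]
  if (length(sides) != 2L)
    stop(sprintf("cannot parse rule %s: '%s'", .ruleRef(label, index), line))
  lhs <- trimws(sides[1L])
  rhsRaw <- trimws(sides[2L])

  # RHS holds the product patterns followed by the rate expression(s);
  # patterns are chained by '+' connectors, everything after the chain is rate
  tok <- strsplit(rhsRaw, "[[:space:]]+")[[1L]]
  patTok <- tok[1L]
  i <- 2L
  while (i <= length(tok)) {
    prev <- patTok
    cur <- tok[i]
    if (cur == "+") {
      if (i == length(tok)) stop(sprintf("dangling '+' in rule %s", .ruleRef(label, index)))
      patTok <- paste0(patTok, "+", tok[i + 1L])
      i <- i + 2L
    } else if (endsWith(prev, "+") || startsWith(cur, "+")) {
      patTok <- paste0(patTok, cur)
      i <- i + 1L
    } else break
  }
  rates <- if (i > length(tok)) character() else
    trimws(strsplit(paste(tok[i:length(tok)], collapse = " "),
                    ",", fixed = TRUE)[[1L]])
  rates <- rates[nzchar(rates)]

  context <- sprintf("rule %s", .ruleRef(label, index))
  reactants <- .parsePatternSide(lhs, context)
  products <- .parsePatternSide(patTok, context)
  .checkBondTags(reactants, context, "reactant")
  .checkBondTags(products, context, "product")
  if (reversible && length(rates) != 1L && length(rates) != 2L)
    warning(sprintf("%s is reversible but has %d rate expression(s)",
                    context, length(rates)), call. = FALSE)

  list(label = label, index = index,
       reactants = reactants, products = products,
       reversible = reversible, rates = rates,
       isSynthesis = length(reactants) == 0L,
       isDegradation = length(products) == 0L)
}

.ruleRef <- function(label, index) {
  if (!is.na(label)) sprintf("'%s'", label) else sprintf("#%d", index)
}

.checkBondTags <- function(side, context, sideName) {
  tags <- character()
  for (cplx in side)
    for (mol in cplx)
      for (comp in mol$components)
        if (!is.na(comp$bond) && grepl("^[0-9]+$", comp$bond))
          tags <- c(tags, comp$bond)
  counts <- table(tags)
  bad <- names(counts)[counts != 2L]
  if (length(bad))
    stop(sprintf("malformed bond tag(s) %s on %s side of %s: each numbered tag must appear exactly twice on one side",
                 paste0("!", bad, collapse = ", "), sideName, context), call. = FALSE)
}

## ---- declaration completion ---------------------------------------------

# auto-declare molecules missing from the molecule types block using the
# maximal observed component signature, and append states seen in rules but
# absent from declarations (with a warning)
.augmentDeclarations <- function(moleculeTypes, ruleList) {
  usage <- list()  # name -> list(order = chr, counts = int by comp name,
                   #              states = list by "comp#occ")
  noteUse <- function(mol) {
    u <- usage[[mol$name]]
    if (is.null(u)) u <- list(order = character(), counts = integer(), states = list())
    seen <- integer()
    for (comp in mol$components) {
      if (!comp$name %in% u$order) u$order <- c(u$order, comp$name)
      occ <- comp$occurrence
      seen[[comp$name]] <- max(occ, if (comp$name %in% names(seen)) seen[[comp$name]] else 0L)
      if (!is.na(comp$state)) {
        key <- paste0(comp$name, "#", occ)
        u$states[[key]] <- union(u$states[[key]], comp$state)
      }
    }
    for (nm in names(seen))
      u$counts[[nm]] <- max(seen[[nm]],
                            if (nm %in% names(u$counts)) u$counts[[nm]] else 0L)
    usage[[mol$name]] <<- u
  }
  for (r in ruleList)
    for (side in list(r$reactants, r$products))
      for (cplx in side)
        for (mol in cplx) noteUse(mol)

  for (mname in names(usage)) {
    u <- usage[[mname]]
    if (!mname %in% names(moleculeTypes)) {
      comps <- list()
      for (cname in u$order) {
        for (occ in seq_len(u$counts[[cname]])) {
          key <- paste0(cname, "#", occ)
          comps[[length(comps) + 1L]] <-
            list(name = cname, occurrence = occ,
                 states = if (is.null(u$states[[key]])) character() else
                   sort(u$states[[key]]))
        }
      }
      if (!length(comps))
        comps <- list(list(name = mname, occurrence = 1L, states = character()))
      moleculeTypes[[mname]] <- list(name = mname, components = comps)
    } else {
      mt <- moleculeTypes[[mname]]
      for (i in seq_along(mt$components)) {
        comp <- mt$components[[i]]
        key <- paste0(comp$name, "#", comp$occurrence)
        extra <- setdiff(u$states[[key]], comp$states)
        if (length(extra)) {
          warning(sprintf("state(s) %s of %s.%s used in rules but not declared; appended to the declaration",
                          paste(extra, collapse = ", "), mname, comp$name),
                  call. = FALSE)
          mt$components[[i]]$states <- c(comp$states, extra)
        }
      }
      moleculeTypes[[mname]] <- mt
    }
  }
  moleculeTypes
}

formatMoleculeType <- function(mt) {
  comps <- vapply(mt$components, function(cc)
    paste0(cc$name, paste0(rep("~", length(cc$states)), cc$states, collapse = "")), "")
  sprintf("%s(%s)", mt$name, paste(comps, collapse = ","))
}
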