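## SMILES reader for the subset needed by 2D additive profiling:
## organic-subset atoms, bracket atoms with charge and explicit H count,
## branches, ring closures (including %nn), aromatic lowercase atoms,
## dot-separated components. Stereo markers (/ \ @ @@) are parsed and
## discarded: the study is 2D and all downstream descriptors are
## stereo-blind. Isotope labels are accepted and ignored.

.AROMATIC_OK <- c("B", "C", "N", "O", "P", "S")

#' Parse a SMILES string into a Molecule
#'
#' Builds the attributed molecular graph and assigns implicit hydrogens from
#' the standard valence model (charge-adjusted for bracket atoms; aromatic
#' atoms reserve one valence unit for the ring pi system). A bond written
#' between two aromatic atoms without an explicit bond symbol is taken as
#' aromatic; exocyclic biaryl single bonds must therefore be written with
#' an explicit \code{-}.
#'
#' @param text a single SMILES string.
#' @param cid,name optional identifier and name attached to the result.
#' @return a [Molecule].
#' @examples
#' parseSmiles("c1ccccc1")   # benzene
#' parseSmiles("CCO")        # ethanol
#' @export
parseSmiles <- function(text, cid = NA_character_, name = NA_character_) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  chars <- strsplit(text, "")[[1]]
  n <- length(chars)
  el <- character(); chg <- integer(); hct <- integer(); arom <- logical()
  bracket <- logical()
  b1 <- integer(); b2 <- integer(); bord <- character()
  prev <- NA_integer_
  stack <- integer()
  rings <- list()        # key: closure number -> list(atom, bond)
  pending <- NA_character_

  addAtom <- function(sym, aromatic, charge, hcount, isBracket) {
    el[length(el) + 1L] <<- sym
    chg[length(chg) + 1L] <<- charge
    hct[length(hct) + 1L] <<- hcount       # NA when to be inferred
    arom[length(arom) + 1L] <<- aromatic
    bracket[length(bracket) + 1L] <<- isBracket
    idx <- length(el)
    if (!is.na(prev)) {
      ord <- if (!is.na(pending)) pending
             else if (arom[prev] && aromatic) "aromatic" else "single"
      b1[length(b1) + 1L] <<- prev; b2[length(b2) + 1L] <<- idx
      bord[length(bord) + 1L] <<- ord
    }
    pending <<- NA_character_
    prev <<- idx
    idx
  }

  closeRing <- function(num) {
    key <- as.character(num)
    if (is.null(rings[[key]])) {
      rings[[key]] <<- list(atom = prev, bond = pending)
      pending <<- NA_character_
    } else {
      open <- rings[[key]]
      rings[[key]] <<- NULL
      ord <- if (!is.na(pending)) pending
             else if (!is.na(open$bond)) open$bond
             else if (arom[open$atom] && arom[prev]) "aromatic" else "single"
      b1[length(b1) + 1L] <<- open$atom; b2[length(b2) + 1L] <<- prev
      bord[length(bord) + 1L] <<- ord
      pending <<- NA_character_
    }
  }

  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) stop("unterminated bracket atom in SMILES at position ", i)
      body <- substr(text, i + 1L, j - 1L)
      m <- regmatches(body, regexec(
        "^([0-9]*)([A-Z][a-z]?|[bcnops])(@{0,2})(H[0-9]*)?([+-][0-9]*|\\+{1,3}|-{1,3})?$",
        body))[[1]]
      if (!length(m)) stop("cannot parse bracket atom [", body, "]")
      sym <- m[3]
      aromatic <- sym %in% c("b", "c", "n", "o", "p", "s")
      if (aromatic) sym <- toupper(sym)
      if (!sym %in% .supportedElements())
        stop("unknown element symbol '", m[3], "' in SMILES")
      hcount <- if (m[5] == "") 0L
                else if (m[5] == "H") 1L else as.integer(substring(m[5], 2L))
      charge <- if (is.na(m[6]) || m[6] == "") 0L else {
        cs <- m[6]
        if (grepl("^[+-][0-9]+$", cs)) as.integer(cs)
        else (if (substr(cs, 1L, 1L) == "+") 1L else -1L) * nchar(cs)
      }
      addAtom(sym, aromatic, charge, hcount, TRUE)
      i <- j + 1L
    } else if (ch %in% c("C", "B") && i < n && chars[i + 1L] %in% c("l", "r") &&
               paste0(ch, chars[i + 1L]) %in% c("Cl", "Br")) {
      addAtom(paste0(ch, chars[i + 1L]), FALSE, 0L, NA_integer_, FALSE)
      i <- i + 2L
    } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
      addAtom(ch, FALSE, 0L, NA_integer_, FALSE)
      i <- i + 1L
    } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
      addAtom(toupper(ch), TRUE, 0L, NA_integer_, FALSE)
      i <- i + 1L
    } else if (ch %in% c("-", "=", "#", ":", "/", "\\")) {
      pending <- switch(ch, "-" = "single", "=" = "double", "#" = "triple",
                        ":" = "aromatic", "/" = "single", "\\" = "single")
      i <- i + 1L
    } else if (grepl("[0-9]", ch)) {
      closeRing(as.integer(ch))
      i <- i + 1L
    } else if (ch == "%") {
      if (i + 2L > n) stop("truncated %nn ring closure in SMILES")
      closeRing(as.integer(substr(text, i + 1L, i + 2L)))
      i <- i + 3L
    } else if (ch == "(") {
      if (is.na(prev)) stop("branch open before any atom in SMILES")
      stack <- c(stack, prev)
      i <- i + 1L
    } else if (ch == ")") {
      if (!length(stack)) stop("unmatched ')' in SMILES")
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (ch == ".") {
      prev <- NA_integer_
      pending <- NA_character_
      i <- i + 1L
    } else if (ch %in% c(" ", "\t")) {
      break
    } else {
      stop("unsupported SMILES token '", ch, "' at position ", i)
    }
  }
  if (length(rings))
    stop("unclosed ring bond(s) in SMILES: ",
         paste(names(rings), collapse = ", "))
  if (!length(el)) stop("empty SMILES")

  mol <- .Molecule(
    atoms = list(element = el, charge = chg,
                 hcount = ifelse(is.na(hct), 0L, hct), aromatic = arom),
    bonds = list(a1 = b1, a2 = b2, order = bord),
    cid = cid, name = name)
  mol@atoms$hcount <- .assignImplicitH(mol, explicit = !is.na(hct))
  .checkValences(mol)
  mol
}

## Implicit hydrogen assignment. `explicit[i]` TRUE means atom i carries an
## authoritative H count (bracket atom / SDF valence) that is kept as is.
.assignImplicitH <- function(mol, explicit = rep(FALSE, nAtoms(mol))) {
  a <- mol@atoms; b <- mol@bonds
  h <- a$hcount
  for (i in seq_len(nrow(a))) {
    if (explicit[i]) next
    inc <- which(b$a1 == i | b$a2 == i)
    if (a$aromatic[i]) {
      used <- length(inc) + 1L   # one valence unit reserved for the pi system
      h[i] <- max(0L, .DEFAULT_VALENCE[[a$element[i]]] - used)
    } else {
      used <- sum(.bondOrderValue(b$order[inc]))
      vals <- .allowedValences(a$element[i], a$charge[i])
      tgt <- vals[vals >= used][1]
      h[i] <- if (is.na(tgt)) 0L else as.integer(tgt - used)
    }
  }
  as.integer(h)
}

.checkValences <- function(mol) {
  a <- mol@atoms; b <- mol@bonds
  for (i in seq_len(nrow(a))) {
    inc <- which(b$a1 == i | b$a2 == i)
    if (a$element[i] %in% .METALS) next
    vals <- .allowedValences(a$element[i], a$charge[i])
    if (a$aromatic[i]) {
      tot <- length(inc) + a$hcount[i]
      ok <- (tot + 1L) %in% vals || tot %in% vals
    } else {
      tot <- sum(.bondOrderValue(b$order[inc])) + a$hcount[i]
      ok <- tot %in% vals
    }
    if (!ok)
      stop(sprintf(
        "valence violation at atom %d (%s%s): %s bonds+H for allowed {%s}",
        i, a$element[i],
        if (a$charge[i] != 0) sprintf("%+d", a$charge[i]) else "",
        format(tot), paste(vals, collapse = ",")))
  }
  invisible(TRUE)
}

#' Read a SMILES table (one molecule per line, optional tab-separated id)
#'
#' @param path file with one SMILES per line; an optional second tab-separated
#'   column is used as the compound id.
#' @return list of [Molecule].
#' @export
readSmiles <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(ln) {
    parts <- strsplit(ln, "\t")[[1]]
    parseSmiles(parts[1], cid = if (length(parts) > 1L) parts[2] else NA)
  })
}
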