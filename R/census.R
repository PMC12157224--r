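## Structural census: molecular formula, weight, atom counts, functional
## groups, ring counts. Multi-component molecules (salts, co-crystals)
## aggregate over components into one sum formula / one census row.

#' Molecular formula in Hill order
#'
#' Carbon first, then hydrogen, then the remaining elements alphabetically;
#' components of a multi-component molecule are merged into one sum formula.
#'
#' @param mol a [Molecule]
#' @return formula string, e.g. \code{"C14H12O3"}.
#' @examples
#' molecularFormula(parseSmiles("CCO"))  # "C2H6O"
#' @rdname molecularFormula
#' @export
setMethod("molecularFormula", "Molecule", function(mol) {
  cnt <- atomCounts(mol)
  cnt <- cnt[cnt > 0]
  ord <- .hillOrder(names(cnt))
  paste0(vapply(ord, function(e)
    paste0(e, if (cnt[[e]] > 1L) cnt[[e]] else ""), character(1)),
    collapse = "")
})

#' Molecular weight
#'
#' Sum of conventional atomic weights (IUPAC 2005 table) over all atoms
#' including implicit hydrogens. Full precision is returned; tables round to
#' two decimals at serialization.
#'
#' @param mol a [Molecule]
#' @return weight in g/mol.
#' @rdname molecularWeight
#' @export
setMethod("molecularWeight", "Molecule", function(mol) {
  cnt <- atomCounts(mol)
  missing <- setdiff(names(cnt), names(.ATOMIC_WEIGHTS))
  if (length(missing))
    stop("no atomic weight entry for: ", paste(missing, collapse = ", "))
  sum(.ATOMIC_WEIGHTS[names(cnt)] * unlist(cnt))
})

#' Atom counts by element, including hydrogens
#'
#' @param mol a [Molecule]
#' @return named integer vector (implicit and explicit H merged under "H").
#' @rdname atomCounts
#' @export
setMethod("atomCounts", "Molecule", function(mol) {
  a <- mol@atoms
  cnt <- table(a$element)
  out <- stats::setNames(as.integer(cnt), names(cnt))
  h <- sum(a$hcount) + if ("H" %in% names(out)) out[["H"]] else 0L
  out <- out[names(out) != "H"]
  if (h > 0L) out[["H"]] <- as.integer(h)
  out[.hillOrder(names(out))]
})

.GROUP_CLASSES <- c("R3N", "RNH2", "R2NH", "ROH", "RCOR", "RCHO", "RCOOH",
                    "RCOOR", "ROR", "ROPO3", "RCCH", "RCN")

#' Functional group census over the twelve additive-relevant classes
#'
#' Counts R3N, RNH2, R2NH, ROH, RCOR (ketone), RCHO, RCOOH, RCOOR (ester),
#' ROR (ether), ROPO3 (phosphate ester), RCCH (terminal alkyne) and RCN
#' (nitrile). Each oxygen or nitrogen is assigned to at most one class with
#' precedence ester > acid > ketone/aldehyde > ether > alcohol, so e.g. the
#' two oxygens of an ester are not additionally counted as ROR/RCOR. Metal
#' carboxylates (zinc stearate) count as RCOOH, consistent with a neutral
#' acid reading of the salt.
#'
#' @param mol a [Molecule]
#' @return named integer vector over the twelve classes.
#' @rdname detectFunctionalGroups
#' @export
setMethod("detectFunctionalGroups", "Molecule", function(mol) {
  a <- mol@atoms; b <- mol@bonds
  n <- nAtoms(mol)
  cnt <- stats::setNames(integer(length(.GROUP_CLASSES)), .GROUP_CLASSES)
  if (!n) return(cnt)
  nbr <- vector("list", n)           # list of (atom, order) pairs
  for (i in seq_len(nrow(b))) {
    nbr[[b$a1[i]]] <- rbind(nbr[[b$a1[i]]], c(b$a2[i], i))
    nbr[[b$a2[i]]] <- rbind(nbr[[b$a2[i]]], c(b$a1[i], i))
  }
  bondTo <- function(v, w) b$order[nbr[[v]][nbr[[v]][, 1] == w, 2][1]]
  neighbors <- function(v) if (is.null(nbr[[v]])) integer() else nbr[[v]][, 1]
  consumedO <- logical(n)

  ## carbonyl-centred classes (precedence ester > acid > ketone/aldehyde)
  for (v in which(a$element == "C" & !a$aromatic)) {
    ns <- neighbors(v)
    if (!length(ns)) next
    dblO <- ns[a$element[ns] == "O" & vapply(ns, function(w)
      bondTo(v, w) == "double", logical(1))]
    if (!length(dblO)) next
    sglO <- ns[a$element[ns] == "O" & vapply(ns, function(w)
      bondTo(v, w) == "single", logical(1))]
    cN <- ns[a$element[ns] == "C"]
    if (length(sglO)) {
      o <- sglO[1]
      oNbr <- setdiff(neighbors(o), v)
      acid <- a$hcount[o] > 0L || a$charge[o] < 0L ||
        any(a$element[oNbr] %in% .METALS)
      if (acid) cnt[["RCOOH"]] <- cnt[["RCOOH"]] + 1L
      else if (any(a$element[oNbr] == "C"))
        cnt[["RCOOR"]] <- cnt[["RCOOR"]] + 1L
      else next
      consumedO[c(dblO[1], o)] <- TRUE
    } else if (length(cN) >= 2L) {
      cnt[["RCOR"]] <- cnt[["RCOR"]] + 1L
      consumedO[dblO[1]] <- TRUE
    } else if (length(cN) == 1L && a$hcount[v] >= 1L) {
      cnt[["RCHO"]] <- cnt[["RCHO"]] + 1L
      consumedO[dblO[1]] <- TRUE
    }
  }
  ## phosphate esters: P carrying a P=O and >= 3 oxygens
  for (v in which(a$element == "P")) {
    ns <- neighbors(v)
    os <- ns[a$element[ns] == "O"]
    hasDbl <- any(vapply(os, function(w) bondTo(v, w) == "double", logical(1)))
    if (hasDbl && length(os) >= 3L) {
      cnt[["ROPO3"]] <- cnt[["ROPO3"]] + 1L
      consumedO[os] <- TRUE
    }
  }
  ## remaining oxygens: ether then alcohol
  for (v in which(a$element == "O" & !a$aromatic & !consumedO)) {
    ns <- neighbors(v)
    sgl <- all(vapply(ns, function(w) bondTo(v, w) == "single", logical(1)))
    if (!sgl) next
    cNbr <- ns[a$element[ns] == "C"]
    if (length(cNbr) == 2L) cnt[["ROR"]] <- cnt[["ROR"]] + 1L
    else if (length(cNbr) == 1L && a$hcount[v] > 0L)
      cnt[["ROH"]] <- cnt[["ROH"]] + 1L
  }
  ## amines: nonaromatic N, all single bonds, not adjacent to a carbonyl C
  for (v in which(a$element == "N" & !a$aromatic & a$charge == 0L)) {
    ns <- neighbors(v)
    if (!all(vapply(ns, function(w) bondTo(v, w) == "single", logical(1))))
      next
    amide <- any(vapply(ns, function(w) {
      w2 <- neighbors(w)
      a$element[w] == "C" && any(a$element[w2] == "O" & vapply(w2, function(u)
        bondTo(w, u) == "double", logical(1)))
    }, logical(1)))
    if (amide) next
    heavyDeg <- length(ns)
    if (heavyDeg == 3L && a$hcount[v] == 0L) cnt[["R3N"]] <- cnt[["R3N"]] + 1L
    else if (heavyDeg == 2L && a$hcount[v] == 1L)
      cnt[["R2NH"]] <- cnt[["R2NH"]] + 1L
    else if (heavyDeg == 1L && a$hcount[v] == 2L)
      cnt[["RNH2"]] <- cnt[["RNH2"]] + 1L
  }
  ## terminal alkynes and nitriles
  for (i in seq_len(nrow(b))) {
    if (b$order[i] != "triple") next
    v <- b$a1[i]; w <- b$a2[i]
    if (a$element[v] == "C" && a$element[w] == "C" &&
        (a$hcount[v] > 0L || a$hcount[w] > 0L))
      cnt[["RCCH"]] <- cnt[["RCCH"]] + 1L
    if (xor(a$element[v] == "N", a$element[w] == "N") &&
        (a$element[v] == "C" || a$element[w] == "C"))
      cnt[["RCN"]] <- cnt[["RCN"]] + 1L
  }
  cnt
})

#' Full structural census of a molecule
#'
#' One call bundling molecular formula, weight, per-element atom counts,
#' functional-group counts and ring counts -- the per-compound
#' characterization table of an additive study set.
#'
#' @param mol a [Molecule]
#' @return list with \code{mf}, \code{mw}, \code{atomCounts},
#'   \code{groupCounts}, \code{ringCount}, \code{aromaticRingCount}.
#' @rdname structuralCensus
#' @export
setMethod("structuralCensus", "Molecule", function(mol) {
  pr <- perceiveRings(mol)
  list(mf = molecularFormula(mol),
       mw = molecularWeight(mol),
       atomCounts = atomCounts(mol),
       groupCounts = detectFunctionalGroups(mol),
       ringCount = pr$ringCount,
       aromaticRingCount = pr$aromaticRingCount)
})

#' Census table for a set of molecules
#'
#' @param mols list of [Molecule]
#' @param elements element columns to report (default: all seen).
#' @return data.frame, one row per molecule: CID, MF, MW and the atom,
#'   group and ring counts.
#' @export
censusTable <- function(mols, elements = NULL) {
  rows <- lapply(mols, structuralCensus)
  if (is.null(elements))
    elements <- .hillOrder(unique(unlist(lapply(rows, function(r)
      names(r$atomCounts)))))
  df <- data.frame(
    cid = vapply(mols, function(m) m@cid, character(1)),
    mf = vapply(rows, `[[`, character(1), "mf"),
    mw = round(vapply(rows, `[[`, numeric(1), "mw"), 2),
    stringsAsFactors = FALSE)
  for (e in elements)
    df[[e]] <- vapply(rows, function(r)
      if (e %in% names(r$atomCounts)) r$atomCounts[[e]] else 0L, integer(1))
  for (g in .GROUP_CLASSES)
    df[[g]] <- vapply(rows, function(r) r$groupCounts[[g]], integer(1))
  df$rings <- vapply(rows, `[[`, integer(1), "ringCount")
  df$aromatics <- vapply(rows, `[[`, integer(1), "aromaticRingCount")
  df
}
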