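#' @import methods
NULL

#' Molecule: an attributed molecular graph
#'
#' 2D molecular graph with typed atoms and bonds. Atoms carry element symbol,
#' formal charge, implicit hydrogen count and an aromatic flag; bonds carry an
#' order class (\code{single}, \code{double}, \code{triple},
#' \code{aromatic}). A molecule may contain several connected components
#' (salts and co-crystals, e.g. zinc stearate).
#'
#' @slot atoms data.frame with columns \code{element}, \code{charge},
#'   \code{hcount}, \code{aromatic}; one row per (heavy) atom.
#' @slot bonds data.frame with columns \code{a1}, \code{a2} (1-based atom
#'   indices) and \code{order}.
#' @slot cid optional compound identifier (PubChem CID as character).
#' @slot name optional chemical name.
#'
#' @examples
#' m <- parseSmiles("CCO")
#' nAtoms(m)
#' @export
setClass("Molecule", representation(
  atoms = "data.frame",
  bonds = "data.frame",
  cid = "character",
  name = "character"
))

setValidity("Molecule", function(object) {
  a <- object@atoms
  b <- object@bonds
  msgs <- character()
  need <- c("element", "charge", "hcount", "aromatic")
  if (!all(need %in% names(a)))
    return(paste("atoms must have columns", paste(need, collapse = ", ")))
  if (!all(c("a1", "a2", "order") %in% names(b)))
    return("bonds must have columns a1, a2, order")
  if (nrow(a) && !all(a$element %in% .supportedElements()))
    msgs <- c(msgs, paste("unsupported element(s):",
                          paste(setdiff(a$element, .supportedElements()),
                                collapse = ", ")))
  if (nrow(b)) {
    if (any(b$a1 < 1L | b$a1 > nrow(a) | b$a2 < 1L | b$a2 > nrow(a)))
      msgs <- c(msgs, "bond endpoint out of range")
    else if (any(b$a1 == b$a2))
      msgs <- c(msgs, "bond endpoints must be distinct")
    else {
      key <- paste(pmin(b$a1, b$a2), pmax(b$a1, b$a2))
      if (anyDuplicated(key)) msgs <- c(msgs, "duplicate bonds")
    }
    if (!all(b$order %in% names(.BOND_ORDERS)))
      msgs <- c(msgs, "bond order must be single/double/triple/aromatic")
  }
  if (nrow(a) && any(a$hcount < 0L)) msgs <- c(msgs, "negative hcount")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

.Molecule <- function(atoms, bonds, cid = NA_character_, name = NA_character_) {
  new("Molecule",
      atoms = data.frame(element = as.character(atoms$element),
                         charge = as.integer(atoms$charge),
                         hcount = as.integer(atoms$hcount),
                         aromatic = as.logical(atoms$aromatic),
                         stringsAsFactors = FALSE),
      bonds = data.frame(a1 = as.integer(bonds$a1), a2 = as.integer(bonds$a2),
                         order = as.character(bonds$order),
                         stringsAsFactors = FALSE),
      cid = as.character(cid), name = as.character(name))
}

#' @describeIn Molecule number of atoms in the graph (heavy atoms; implicit
#'   hydrogens are counted separately through \code{atomCounts}).
#' @param mol a \code{Molecule}
#' @export
nAtoms <- function(mol) nrow(mol@atoms)

#' @describeIn Molecule number of bonds.
#' @export
nBonds <- function(mol) nrow(mol@bonds)

setMethod("show", "Molecule", function(object) {
  cat(sprintf("Molecule%s: %d atoms, %d bonds, MF %s\n",
              if (!is.na(object@cid)) paste0(" CID ", object@cid) else "",
              nAtoms(object), nBonds(object),
              tryCatch(molecularFormula(object), error = function(e) "?")))
})

#' Result of a maximum-common-substructure search
#'
#' @slot c heavy-atom size of the common substructure.
#' @slot mapping two-column integer matrix of matched atom indices
#'   (query, target).
#' @slot a,b heavy-atom counts of the two molecules.
#' @slot exhausted FALSE when the branch-and-bound search was truncated by
#'   the timeout, in which case \code{c} is the best size found.
#'
#' @seealso [mcs()], [ocCoef()], [tcCoef()]
#' @export
setClass("MCSResult", representation(
  c = "integer", mapping = "matrix", a = "integer", b = "integer",
  exhausted = "logical"
))

setValidity("MCSResult", function(object) {
  if (object@c > min(object@a, object@b)) "c exceeds min(a, b)" else TRUE
})

setMethod("show", "MCSResult", function(object) {
  cat(sprintf("MCSResult: c = %d (a = %d, b = %d), OC = %.2f, TC = %.2f%s\n",
              object@c, object@a, object@b, ocCoef(object), tcCoef(object),
              if (!object@exhausted) " [search truncated]" else ""))
})

#' Symmetric similarity matrix over a compound set
#'
#' @slot ids ordered compound identifiers.
#' @slot values symmetric numeric matrix in [0, 1] with unit diagonal.
#' @slot cutoff reporting threshold: emitters blank cells below it
#'   (\code{NA} for no masking). Stored values are never masked.
#'
#' @export
setClass("SimilarityMatrix", representation(
  ids = "character", values = "matrix", cutoff = "numeric"
))

setValidity("SimilarityMatrix", function(object) {
  v <- object@values
  if (nrow(v) != length(object@ids) || ncol(v) != length(object@ids))
    return("values dimension does not match ids")
  if (nrow(v)) {
    if (max(abs(v - t(v))) > 1e-8) return("matrix must be symmetric")
    if (max(abs(diag(v) - 1)) > 1e-8) return("diagonal must be 1")
  }
  TRUE
})

setMethod("show", "SimilarityMatrix", function(object) {
  cat(sprintf("SimilarityMatrix: %d compounds%s\n", length(object@ids),
              if (!is.na(object@cutoff))
                sprintf(", reporting cutoff %.2f", object@cutoff) else ""))
})

#' @describeIn SimilarityMatrix identifiers of the compounds (row order).
#' @param x a \code{SimilarityMatrix}
#' @export
simIds <- function(x) x@ids

#' @describeIn SimilarityMatrix the full (unmasked) similarity values.
#' @export
simValues <- function(x) {
  v <- x@values
  dimnames(v) <- list(x@ids, x@ids)
  v
}

.SimilarityMatrix <- function(ids, values, cutoff = NA_real_) {
  dimnames(values) <- list(ids, ids)
  new("SimilarityMatrix", ids = as.character(ids), values = values,
      cutoff = as.numeric(cutoff))
}
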