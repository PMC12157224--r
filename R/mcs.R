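## Maximum common substructure search and the OC / TC coefficients derived
## from it. Sizes count heavy atoms only; Kekule rings are normalized to
## aromatic form before matching so alternation artifacts cannot split an
## aromatic match.

.heavyGraph <- function(mol) {
  mol <- normalizeAromaticity(mol)
  a <- mol@atoms; b <- mol@bonds
  keep <- which(a$element != "H")
  remap <- integer(nrow(a)); remap[keep] <- seq_along(keep)
  sel <- b$a1 %in% keep & b$a2 %in% keep
  list(elements = a$element[keep],
       bonds = cbind(remap[b$a1[sel]], remap[b$a2[sel]],
                     c(single = 1L, double = 2L, triple = 3L,
                       aromatic = 4L)[b$order[sel]]))
}

#' Maximum common substructure of two molecules
#'
#' Branch-and-bound search for the largest connected common induced
#' subgraph of the heavy-atom graphs, matching atoms by element and bonds
#' by order class. \code{au}/\code{bu} budgets allow that many atom-label /
#' bond-label mismatches ("flexible" matching); the default (0, 0) is exact
#' matching. The search is order-symmetric in its reported size and
#' coefficients.
#'
#' @param A,B [Molecule]s.
#' @param au,bu atom / bond mismatch budgets (default 0).
#' @param timeout wall-clock budget in seconds; on expiry the best result
#'   found is returned with \code{exhausted = FALSE} (never an error).
#' @return an [MCSResult].
#' @examples
#' r <- mcs(parseSmiles("c1ccccc1"), parseSmiles("c1ccccc1"))
#' ocCoef(r); tcCoef(r)
#' @export
mcs <- function(A, B, au = 0L, bu = 0L, timeout = 60) {
  ga <- .heavyGraph(A); gb <- .heavyGraph(B)
  a <- length(ga$elements); b <- length(gb$elements)
  swap <- a > b          # search from the smaller side
  if (swap) { tmp <- ga; ga <- gb; gb <- tmp }
  lev <- unique(c(ga$elements, gb$elements))
  res <- .mcsSearch(match(ga$elements, lev), ga$bonds,
                    match(gb$elements, lev), gb$bonds,
                    as.integer(au), as.integer(bu), as.numeric(timeout))
  mapping <- res$mapping
  if (swap) mapping <- mapping[, c(2L, 1L), drop = FALSE]
  colnames(mapping) <- c("A", "B")
  new("MCSResult", c = as.integer(res$c), mapping = mapping,
      a = as.integer(a), b = as.integer(b),
      exhausted = as.logical(res$exhausted))
}

#' Overlap coefficient of an MCS result
#'
#' c / min(a, b): 1 means the smaller molecule embeds completely in the
#' larger one.
#'
#' @param r an [MCSResult].
#' @return value in [0, 1].
#' @rdname ocCoef
#' @export
setMethod("ocCoef", "MCSResult", function(r) {
  if (min(r@a, r@b) == 0L) stop("overlap coefficient undefined for an empty molecule")
  r@c / min(r@a, r@b)
})

#' MCS-based Tanimoto coefficient
#'
#' c / (a + b - c) on heavy-atom counts.
#'
#' @param r an [MCSResult].
#' @return value in [0, 1].
#' @rdname tcCoef
#' @export
setMethod("tcCoef", "MCSResult", function(r) {
  if (r@a + r@b == 0L) stop("Tanimoto coefficient undefined for empty molecules")
  r@c / (r@a + r@b - r@c)
})

#' Pairwise MCS similarity matrices
#'
#' Computes the MCS for every unordered pair once and returns the OC and TC
#' matrices plus the per-pair search-completion flags. A per-pair timeout
#' truncates that pair's search (flag FALSE) without aborting the batch.
#'
#' @param mols list of [Molecule] (>= 2).
#' @param au,bu mismatch budgets, see [mcs()].
#' @param timeout per-pair budget in seconds.
#' @param cutoff reporting cutoff stored with the matrices.
#' @return list with [SimilarityMatrix] elements \code{oc}, \code{tc} and a
#'   logical matrix \code{exhausted}.
#' @export
mcsMatrix <- function(mols, au = 0L, bu = 0L, timeout = 5, cutoff = NA) {
  stopifnot(length(mols) >= 2L)
  ids <- vapply(seq_along(mols), function(i) {
    cid <- mols[[i]]@cid
    if (is.na(cid)) as.character(i) else cid
  }, character(1))
  n <- length(mols)
  oc <- diag(nrow = n); tc <- diag(nrow = n)
  ex <- matrix(TRUE, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    r <- mcs(mols[[i]], mols[[j]], au = au, bu = bu, timeout = timeout)
    oc[i, j] <- oc[j, i] <- ocCoef(r)
    tc[i, j] <- tc[j, i] <- tcCoef(r)
    ex[i, j] <- ex[j, i] <- r@exhausted
  }
  list(oc = .SimilarityMatrix(ids, oc, cutoff),
       tc = .SimilarityMatrix(ids, tc, cutoff),
       exhausted = ex)
}
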