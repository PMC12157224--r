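## Carhart atom pairs: two typed heavy atoms plus the length of the
## shortest bond path between them. An atom's type is (element, number of
## heavy neighbors, pi-electron count); the unique set of pairs is the
## molecule's fingerprint and similarity is the Tanimoto coefficient on
## those sets.

## per-atom pi electron count: 1 for aromatic atoms, else 1 per double bond,
## 2 per triple bond (capped at 2)
.piElectrons <- function(mol) {
  a <- mol@atoms; b <- mol@bonds
  pi <- integer(nAtoms(mol))
  for (i in seq_len(nrow(b))) {
    add <- switch(b$order[i], double = 1L, triple = 2L, 0L)
    if (add) {
      pi[b$a1[i]] <- pi[b$a1[i]] + add
      pi[b$a2[i]] <- pi[b$a2[i]] + add
    }
  }
  pi[a$aromatic] <- 1L
  pmin(pi, 2L)
}

## all-pairs shortest-path distances on the heavy-atom graph (BFS per atom)
.bondDistances <- function(mol) {
  n <- nAtoms(mol)
  adj <- .adjacency(mol)
  d <- matrix(NA_integer_, n, n)
  for (s in seq_len(n)) {
    d[s, s] <- 0L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) if (is.na(d[s, w])) {
        d[s, w] <- d[s, v] + 1L
        queue <- c(queue, w)
      }
    }
  }
  d
}

#' Atom-pair fingerprint of a molecule
#'
#' Heavy atoms are typed by (element, heavy-atom degree, pi-electron count);
#' every unordered pair of heavy atoms in the same connected component
#' yields one descriptor with its shortest-path bond distance. The
#' descriptor collection is counted (multiset) - similarity uses
#' min-count intersections, the convention that reproduces published
#' atom-pair Tanimoto tables; \code{unique()} gives the underlying set.
#'
#' @param mol a [Molecule]
#' @return sorted character vector of canonical pair descriptors, one entry
#'   per atom pair (duplicates meaningful); a single-heavy-atom molecule
#'   yields an empty fingerprint.
#' @examples
#' unique(atomPairSet(parseSmiles("CCO")))   # three distinct pairs
#' @rdname atomPairSet
#' @export
setMethod("atomPairSet", "Molecule", function(mol) {
  n <- nAtoms(mol)
  if (n < 2L) return(character())
  a <- mol@atoms
  deg <- integer(n)
  b <- mol@bonds
  for (i in seq_len(nrow(b))) {
    deg[b$a1[i]] <- deg[b$a1[i]] + 1L
    deg[b$a2[i]] <- deg[b$a2[i]] + 1L
  }
  pi <- .piElectrons(mol)
  type <- sprintf("%s.%d.%d", a$element, deg, pi)
  d <- .bondDistances(mol)
  pairs <- character()
  k <- 0L
  out <- character(n * (n - 1L) / 2L)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (is.na(d[i, j])) next    # different components
    t1 <- type[i]; t2 <- type[j]
    if (t2 < t1) { tmp <- t1; t1 <- t2; t2 <- tmp }
    k <- k + 1L
    out[k] <- paste(t1, t2, d[i, j], sep = "|")
  }
  sort(out[seq_len(k)])
})

#' Tanimoto similarity of two atom-pair fingerprints
#'
#' c / (m1 + m2 - c), where m1 and m2 are the fingerprint sizes and c the
#' number of pairs present in both (min-count multiset intersection). Two
#' empty fingerprints give 0 with a warning.
#'
#' @param A,B atom-pair fingerprints from [atomPairSet()] (or [Molecule]s).
#' @return similarity in [0, 1].
#' @export
tanimotoAP <- function(A, B) {
  if (is(A, "Molecule")) A <- atomPairSet(A)
  if (is(B, "Molecule")) B <- atomPairSet(B)
  if (!length(A) && !length(B)) {
    warning("both atom-pair sets empty; similarity defined as 0")
    return(0)
  }
  ta <- table(A); tb <- table(B)
  common <- intersect(names(ta), names(tb))
  cc <- sum(pmin(ta[common], tb[common]))
  cc / (length(A) + length(B) - cc)
}

#' Pairwise atom-pair Tanimoto matrix
#'
#' @param mols list of [Molecule] (>= 1).
#' @param cutoff reporting cutoff stored with the matrix (default 0.30);
#'   values themselves are kept at full precision.
#' @return a [SimilarityMatrix].
#' @export
apMatrix <- function(mols, cutoff = 0.30) {
  stopifnot(length(mols) >= 1L)
  ids <- vapply(seq_along(mols), function(i) {
    cid <- mols[[i]]@cid
    if (is.na(cid)) as.character(i) else cid
  }, character(1))
  sets <- lapply(mols, atomPairSet)
  n <- length(mols)
  v <- diag(nrow = n)
  if (n > 1L) for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    v[i, j] <- v[j, i] <- tanimotoAP(sets[[i]], sets[[j]])
  .SimilarityMatrix(ids, v, cutoff)
}
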