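## Brute-force MCS oracle: exhaustive enumeration of the connected induced
## subgraphs of the smaller molecule (largest first), each tested for an
## induced, element- and bond-class-preserving embedding into the larger
## molecule by plain backtracking. Exact but exponential; restricted to
## small molecules and used to certify the branch-and-bound search.

#' Exhaustive maximum-common-substructure oracle
#'
#' @param A,B [Molecule]s with at most \code{maxAtoms} heavy atoms each.
#' @param maxAtoms size guard (default 12).
#' @return integer: the exact maximum common connected induced subgraph
#'   size in heavy atoms.
#' @export
oracleMcs <- function(A, B, maxAtoms = 12L) {
  ga <- .heavyGraph(A); gb <- .heavyGraph(B)
  if (length(ga$elements) > length(gb$elements)) { tmp <- ga; ga <- gb; gb <- tmp }
  na <- length(ga$elements); nb <- length(gb$elements)
  if (na > maxAtoms || nb > maxAtoms)
    stop("oracle restricted to molecules with <= ", maxAtoms, " heavy atoms")
  if (na == 0L || nb == 0L) return(0L)
  adjA <- matrix(0L, na, na); adjB <- matrix(0L, nb, nb)
  for (r in seq_len(nrow(ga$bonds)))
    adjA[ga$bonds[r, 1], ga$bonds[r, 2]] <- adjA[ga$bonds[r, 2], ga$bonds[r, 1]] <-
      ga$bonds[r, 3]
  for (r in seq_len(nrow(gb$bonds)))
    adjB[gb$bonds[r, 1], gb$bonds[r, 2]] <- adjB[gb$bonds[r, 2], gb$bonds[r, 1]] <-
      gb$bonds[r, 3]
  subsets <- .connectedSubsets(adjA)
  sizes <- lengths(subsets)
  for (sz in sort(unique(sizes), decreasing = TRUE)) {
    for (s in subsets[sizes == sz]) {
      if (.embedsInduced(s, adjA, ga$elements, adjB, gb$elements))
        return(as.integer(sz))
    }
  }
  0L
}

## all connected vertex subsets (each discovered once: extensions restricted
## to neighbors of the current set with index > the seed)
.connectedSubsets <- function(adj) {
  n <- nrow(adj)
  out <- list()
  grow <- function(set, candidates) {
    out[[length(out) + 1L]] <<- set
    while (length(candidates)) {
      v <- candidates[1]
      candidates <- candidates[-1]
      nbrs <- which(adj[v, ] != 0L)
      newCand <- union(candidates, setdiff(nbrs[nbrs > set[1]],
                                           c(set, v)))
      grow(c(set, v), newCand)
    }
  }
  for (s in seq_len(n)) {
    nbrs <- which(adj[s, ] != 0L)
    grow(s, nbrs[nbrs > s])
  }
  out
}

## does the induced subgraph of A on `set` embed (induced, label-preserving)
## into B?
.embedsInduced <- function(set, adjA, elA, adjB, elB) {
  m <- length(set)
  nb <- length(elB)
  assign <- integer(m)
  usedB <- logical(nb)
  bt <- function(pos) {
    if (pos > m) return(TRUE)
    v <- set[pos]
    for (w in seq_len(nb)) {
      if (usedB[w] || elB[w] != elA[v]) next
      ok <- TRUE
      for (p in seq_len(pos - 1L)) {
        if (adjA[v, set[p]] != adjB[w, assign[p]]) { ok <- FALSE; break }
      }
      if (!ok) next
      assign[pos] <<- w; usedB[w] <<- TRUE
      if (bt(pos + 1L)) return(TRUE)
      usedB[w] <<- FALSE
    }
    FALSE
  }
  bt(1L)
}
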