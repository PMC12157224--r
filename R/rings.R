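## Ring perception: connected components, a smallest-set-of-smallest-rings
## (SSSR) basis of the cycle space, and aromaticity. SSSR candidates are the
## shortest cycles through each cyclic edge; a greedy GF(2)-independent
## selection by increasing size realizes the cycle-space dimension
## (bonds - atoms + components), which is exact for molecule-sized graphs.

.adjacency <- function(mol) {
  n <- nAtoms(mol)
  adj <- vector("list", n)
  b <- mol@bonds
  for (i in seq_len(nrow(b))) {
    adj[[b$a1[i]]] <- c(adj[[b$a1[i]]], b$a2[i])
    adj[[b$a2[i]]] <- c(adj[[b$a2[i]]], b$a1[i])
  }
  adj
}

#' Connected components of a molecular graph
#'
#' @param mol a [Molecule]
#' @return integer vector of component labels (1-based, first-occurrence
#'   order), one per atom.
#' @export
connectedComponents <- function(mol) {
  n <- nAtoms(mol)
  adj <- .adjacency(mol)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s]) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) if (!comp[w]) { comp[w] <- cur; queue <- c(queue, w) }
    }
  }
  comp
}

## BFS shortest path u -> v avoiding edge (u, v); NULL when none.
.shortestPathAvoiding <- function(adj, u, v) {
  n <- length(adj)
  parent <- integer(n); seen <- logical(n)
  seen[u] <- TRUE; queue <- u
  while (length(queue)) {
    x <- queue[1]; queue <- queue[-1]
    for (w in adj[[x]]) {
      if (x == u && w == v) next
      if (!seen[w]) {
        seen[w] <- TRUE; parent[w] <- x
        if (w == v) {
          path <- v
          while (path[1] != u) path <- c(parent[path[1]], path)
          return(path)
        }
        queue <- c(queue, w)
      }
    }
  }
  NULL
}

#' Perceive rings and aromaticity
#'
#' Returns an SSSR ring basis together with per-ring aromaticity. A ring is
#' aromatic when (a) all its atoms carry the aromatic flag from input, or
#' (b) every ring atom is sp2-capable and the per-ring Hueckel pi count
#' (1 per atom of an in-ring double bond, 2 for a heteroatom donating a lone
#' pair, 0 for a carbon with an exocyclic double bond) satisfies 4n+2.
#'
#' @param mol a [Molecule]
#' @return list with \code{ringCount}, \code{aromaticRingCount},
#'   \code{rings} (list of atom index vectors) and \code{aromatic}
#'   (logical per ring).
#' @rdname perceiveRings
#' @export
setMethod("perceiveRings", "Molecule", function(mol) {
  n <- nAtoms(mol)
  b <- mol@bonds
  comp <- if (n) connectedComponents(mol) else integer()
  dim <- nrow(b) - n + length(unique(comp))
  if (dim <= 0L)
    return(list(ringCount = 0L, aromaticRingCount = 0L,
                rings = list(), aromatic = logical()))
  adj <- .adjacency(mol)
  ## candidate cycles (as ordered vertex sequences): the shortest cycle
  ## through each edge, plus the BFS fundamental cycles -- the latter alone
  ## span the cycle space, so the greedy selection always reaches the full
  ## dimension
  cand <- list()
  for (i in seq_len(nrow(b))) {
    p <- .shortestPathAvoiding(adj, b$a1[i], b$a2[i])
    if (!is.null(p)) cand[[length(cand) + 1L]] <- p
  }
  cand <- c(cand, .fundamentalCycles(mol, adj))
  cand <- cand[!duplicated(lapply(cand, sort))]
  cand <- cand[order(lengths(cand))]
  ## greedy GF(2)-independent selection over exact edge incidence vectors
  basis <- matrix(FALSE, nrow = 0L, ncol = nrow(b))
  sel <- list()
  for (r in cand) {
    if (length(sel) >= dim) break
    red <- .cycleEdgeVector(r, b)
    for (j in seq_len(nrow(basis))) {
      piv <- which(basis[j, ])[1]
      if (red[piv]) red <- xor(red, basis[j, ])
    }
    if (any(red)) {
      basis <- rbind(basis, red)
      sel[[length(sel) + 1L]] <- sort(r)
    }
  }
  arom <- vapply(sel, function(r) .ringIsAromatic(mol, r), logical(1))
  list(ringCount = length(sel), aromaticRingCount = sum(arom),
       rings = sel, aromatic = arom)
})

## fundamental cycles of a BFS spanning forest
.fundamentalCycles <- function(mol, adj) {
  n <- nAtoms(mol)
  b <- mol@bonds
  parent <- rep(NA_integer_, n)
  depth <- integer(n)
  seen <- logical(n)
  for (s in seq_len(n)) {
    if (seen[s]) next
    seen[s] <- TRUE
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) if (!seen[w]) {
        seen[w] <- TRUE; parent[w] <- v; depth[w] <- depth[v] + 1L
        queue <- c(queue, w)
      }
    }
  }
  treeEdge <- function(u, v) (!is.na(parent[u]) && parent[u] == v) ||
    (!is.na(parent[v]) && parent[v] == u)
  out <- list()
  for (i in seq_len(nrow(b))) {
    u <- b$a1[i]; v <- b$a2[i]
    if (treeEdge(u, v)) next
    pu <- u; pv <- v
    pathU <- u; pathV <- v
    while (depth[pu] > depth[pv]) { pu <- parent[pu]; pathU <- c(pathU, pu) }
    while (depth[pv] > depth[pu]) { pv <- parent[pv]; pathV <- c(pathV, pv) }
    while (pu != pv) {
      pu <- parent[pu]; pathU <- c(pathU, pu)
      pv <- parent[pv]; pathV <- c(pathV, pv)
    }
    ## ordered cycle: apex..u, then the closing edge, then v..(below apex)
    out[[length(out) + 1L]] <- c(rev(pathU), pathV[-length(pathV)])
  }
  out
}

## exact edge incidence vector of an ordered vertex cycle
.cycleEdgeVector <- function(cycle, b) {
  on <- logical(nrow(b))
  m <- length(cycle)
  for (i in seq_len(m)) {
    u <- cycle[i]; v <- cycle[if (i == m) 1L else i + 1L]
    hit <- which((b$a1 == u & b$a2 == v) | (b$a1 == v & b$a2 == u))
    on[hit] <- TRUE
  }
  on
}

.ringIsAromatic <- function(mol, ring) {
  a <- mol@atoms; b <- mol@bonds
  if (all(a$aromatic[ring])) return(TRUE)
  if (any(a$aromatic[ring])) return(FALSE)
  inRing <- logical(nAtoms(mol)); inRing[ring] <- TRUE
  pi <- 0L
  for (v in ring) {
    inc <- which(b$a1 == v | b$a2 == v)
    dbl <- inc[b$order[inc] == "double"]
    el <- a$element[v]
    if (length(dbl)) {
      other <- ifelse(b$a1[dbl] == v, b$a2[dbl], b$a1[dbl])
      if (any(inRing[other])) pi <- pi + 1L
      else if (el == "C") pi <- pi + 0L   # exocyclic C=X: sp2, no pi donated
      else return(FALSE)
    } else if (el %in% c("N", "O", "S")) {
      pi <- pi + 2L                        # lone-pair donor
    } else {
      return(FALSE)                        # sp3 carbon
    }
  }
  pi >= 2L && (pi - 2L) %% 4L == 0L
}

#' Normalize Kekule rings to aromatic form
#'
#' Rewrites every perceived aromatic ring to aromatic bonds and flags its
#' atoms, so that alternating Kekule structures and aromatic-form input
#' compare equal under substructure matching.
#'
#' @param mol a [Molecule]
#' @return the normalized [Molecule]
#' @export
normalizeAromaticity <- function(mol) {
  pr <- perceiveRings(mol)
  if (!any(pr$aromatic)) return(mol)
  a <- mol@atoms; b <- mol@bonds
  for (k in which(pr$aromatic)) {
    ring <- pr$rings[[k]]
    a$aromatic[ring] <- TRUE
    inRing <- logical(nrow(a)); inRing[ring] <- TRUE
    sel <- inRing[b$a1] & inRing[b$a2]
    b$order[sel] <- "aromatic"
  }
  out <- mol
  out@atoms <- a
  out@bonds <- b
  out
}
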