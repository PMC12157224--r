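## Seeded synthetic generators: random valence-correct molecular graphs,
## planted-core MCS pairs with label-distinct decorations, and Gaussian
## feature matrices with planted clusters. All generators are pure
## functions of their seed through R's Mersenne-Twister stream, so outputs
## are identical across platforms.

#' Random valence-correct molecule
#'
#' Grows a random spanning tree over \code{nHeavy} atoms (elements sampled
#' from \code{heteroProbs}), then adds random ring-closing single bonds
#' with probability \code{ringProb} per candidate, respecting valences.
#' Occasional double bonds are introduced where both endpoints have two
#' free valences.
#'
#' @param seed integer seed.
#' @param nHeavy number of heavy atoms (>= 1).
#' @param ringProb probability of accepting each candidate ring closure.
#' @param heteroProbs named sampling weights over elements
#'   (default C-rich with N, O, S).
#' @param doubleProb probability of upgrading an eligible bond to a double
#'   bond.
#' @return a connected [Molecule].
#' @export
randomMolecule <- function(seed, nHeavy, ringProb = 0.15,
                           heteroProbs = c(C = 0.7, N = 0.1, O = 0.15,
                                           S = 0.05),
                           doubleProb = 0.1) {
  stopifnot(nHeavy >= 1L)
  set.seed(as.integer(seed))
  el <- sample(names(heteroProbs), nHeavy, replace = TRUE,
               prob = heteroProbs)
  cap <- vapply(el, function(e) .DEFAULT_VALENCE[[e]], integer(1))
  if (all(cap[1] < 1) && nHeavy > 1L) stop("infeasible valence request")
  b1 <- integer(0); b2 <- integer(0); ord <- character(0)
  used <- integer(nHeavy)
  if (nHeavy > 1L) {
    for (v in 2:nHeavy) {
      open <- which(used[seq_len(v - 1L)] < cap[seq_len(v - 1L)])
      if (!length(open)) stop("infeasible valence request")
      u <- if (length(open) == 1L) open else sample(open, 1L)
      b1 <- c(b1, u); b2 <- c(b2, v); ord <- c(ord, "single")
      used[u] <- used[u] + 1L; used[v] <- used[v] + 1L
    }
    ## ring closures
    for (v in seq_len(nHeavy - 1L)) for (w in (v + 1L):nHeavy) {
      if (any(b1 == v & b2 == w)) next
      if (used[v] < cap[v] && used[w] < cap[w] &&
          stats::runif(1) < ringProb) {
        b1 <- c(b1, v); b2 <- c(b2, w); ord <- c(ord, "single")
        used[v] <- used[v] + 1L; used[w] <- used[w] + 1L
      }
    }
    ## double-bond upgrades
    for (i in seq_along(b1)) {
      v <- b1[i]; w <- b2[i]
      if (used[v] < cap[v] && used[w] < cap[w] &&
          stats::runif(1) < doubleProb) {
        ord[i] <- "double"
        used[v] <- used[v] + 1L; used[w] <- used[w] + 1L
      }
    }
  }
  mol <- .Molecule(
    atoms = list(element = el, charge = integer(nHeavy),
                 hcount = integer(nHeavy),
                 aromatic = logical(nHeavy)),
    bonds = list(a1 = b1, a2 = b2, order = ord))
  mol@atoms$hcount <- .assignImplicitH(mol)
  .checkValences(mol)
  mol
}

#' Planted-core MCS pair
#'
#' Two molecules sharing an identical planted core; decorations use
#' halogens absent from the core (Cl on A, Br on B), so no common subgraph
#' can extend beyond the core and the exact MCS size equals the core size.
#'
#' @param seed integer seed.
#' @param coreSize heavy atoms of the shared core (>= 2).
#' @param decorationsA,decorationsB number of halogen decorations to
#'   attach to each copy.
#' @return list with \code{molA}, \code{molB}, \code{coreSize}.
#' @export
plantedMcsPair <- function(seed, coreSize, decorationsA = 2L,
                           decorationsB = 2L) {
  stopifnot(coreSize >= 2L)
  set.seed(as.integer(seed))
  core <- randomMolecule(seed = sample.int(2^30, 1L), nHeavy = coreSize,
                         ringProb = 0.1,
                         heteroProbs = c(C = 0.8, N = 0.1, O = 0.1),
                         doubleProb = 0)
  decorate <- function(mol, halogen, count) {
    a <- mol@atoms; b <- mol@bonds
    for (d in seq_len(count)) {
      used <- integer(nrow(a))
      for (i in seq_len(nrow(b))) {
        used[b$a1[i]] <- used[b$a1[i]] + .bondOrderValue(b$order[i])
        used[b$a2[i]] <- used[b$a2[i]] + .bondOrderValue(b$order[i])
      }
      cap <- vapply(a$element, function(e) .DEFAULT_VALENCE[[e]], integer(1))
      open <- which(used < cap & a$element %in% c("C", "N", "O", "S"))
      if (!length(open)) break
      host <- if (length(open) == 1L) open else sample(open, 1L)
      a <- rbind(a, data.frame(element = halogen, charge = 0L, hcount = 0L,
                               aromatic = FALSE))
      b <- rbind(b, data.frame(a1 = host, a2 = nrow(a), order = "single"))
    }
    out <- .Molecule(atoms = a, bonds = b)
    out@atoms$hcount <- .assignImplicitH(out)
    out
  }
  molA <- decorate(core, "Cl", decorationsA)
  molB <- decorate(core, "Br", decorationsB)
  list(molA = molA, molB = molB, coreSize = coreSize)
}

#' Gaussian feature matrix with planted clusters
#'
#' Cluster centers sit at mutual Euclidean distance \code{separation}
#' (regular simplex construction), with isotropic Gaussian noise of
#' standard deviation \code{sd}.
#'
#' @param seed integer seed.
#' @param k number of clusters.
#' @param nPerCluster observations per cluster.
#' @param dim feature dimension (>= k - 1).
#' @param separation center-to-center distance.
#' @param sd within-cluster standard deviation per coordinate.
#' @return list with matrix \code{X} (rownames obs1..) and integer
#'   \code{labels}.
#' @export
gaussianFeatureMatrix <- function(seed, k = 3L, nPerCluster = 10L,
                                  dim = max(2L, k - 1L), separation = 6,
                                  sd = 1) {
  stopifnot(k >= 1L, dim >= k - 1L || k == 1L)
  set.seed(as.integer(seed))
  ## regular simplex with k vertices, edge length = separation: center the
  ## k identity vectors (all pairwise distances sqrt(2)), rotate onto their
  ## k-1 principal axes, rescale
  centers <- matrix(0, k, dim)
  if (k > 1L) {
    E <- scale(diag(k), center = TRUE, scale = FALSE)
    sv <- svd(E, nu = k, nv = 0)
    coords <- (sv$u %*% diag(sv$d, k))[, seq_len(k - 1L), drop = FALSE]
    centers[, seq_len(k - 1L)] <- coords * (separation / sqrt(2))
  }
  n <- k * nPerCluster
  labels <- rep(seq_len(k), each = nPerCluster)
  X <- centers[labels, , drop = FALSE] +
    matrix(stats::rnorm(n * dim, sd = sd), n, dim)
  rownames(X) <- sprintf("obs%d", seq_len(n))
  list(X = X, labels = labels)
}
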