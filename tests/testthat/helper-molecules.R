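## Shared fixtures built in code. The study molecules and their MCS matrix
## are computed once per test run.

.cache <- new.env(parent = emptyenv())

fixtureMols <- function() {
  if (is.null(.cache$mols)) .cache$mols <- studyMolecules()
  .cache$mols
}

fixtureMcs <- function() {
  if (is.null(.cache$mcs))
    .cache$mcs <- mcsMatrix(fixtureMols(), timeout = 10)
  .cache$mcs
}

## minimum-spanning-tree edge weights (Prim), the oracle for single linkage
mstEdgeWeights <- function(D) {
  n <- nrow(D)
  inTree <- c(TRUE, rep(FALSE, n - 1L))
  w <- numeric(0)
  best <- D[1, ]
  for (step in seq_len(n - 1L)) {
    cand <- which(!inTree)
    v <- cand[which.min(best[cand])]
    w <- c(w, best[v])
    inTree[v] <- TRUE
    best <- pmin(best, D[v, ])
  }
  unname(sort(w))
}

## all set partitions of 1..n (restricted growth strings)
allPartitions <- function(n) {
  out <- list()
  rec <- function(a, mx) {
    i <- length(a) + 1L
    if (i > n) { out[[length(out) + 1L]] <<- a; return() }
    for (g in seq_len(mx + 1L)) rec(c(a, g), max(mx, g))
  }
  rec(integer(0), 0L)
  out
}

## direct-formula oracles for silhouette and Dunn
oracleSilhouette <- function(D, labels) {
  n <- nrow(D)
  mean(vapply(seq_len(n), function(i) {
    own <- setdiff(which(labels == labels[i]), i)
    if (!length(own)) return(0)
    a <- mean(D[i, own])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(g) mean(D[i, labels == g]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1)))
}

oracleDunn <- function(D, labels) {
  groups <- unique(labels)
  diam <- max(vapply(groups, function(g) {
    idx <- which(labels == g)
    if (length(idx) < 2L) 0 else max(D[idx, idx])
  }, numeric(1)))
  if (diam == 0) return(0)
  sep <- min(vapply(utils::combn(groups, 2, simplify = FALSE), function(p)
    min(D[labels == p[1], labels == p[2]]), numeric(1)))
  sep / diam
}

randomDistanceMatrix <- function(n, seed) {
  set.seed(seed)
  X <- matrix(stats::rnorm(n * 3), n)
  as.matrix(stats::dist(X))
}
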