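## Clustering: similarity-to-distance transform, binning (single-linkage
## threshold) clustering, hierarchical clustering with cophenetic linkage
## selection, dendrogram cuts, and a seeded k-means with k-means++ starts.
## Agglomeration itself is delegated to stats::hclust / stats::kmeans; the
## surrounding selection and validation logic is implemented here.

.asDistanceMatrix <- function(D) {
  if (is(D, "SimilarityMatrix")) return(distanceFromSimilarity(D))
  if (inherits(D, "dist")) D <- as.matrix(D)
  stopifnot(is.matrix(D), nrow(D) == ncol(D))
  if (max(abs(D - t(D))) > 1e-8) stop("distance matrix must be symmetric")
  if (any(diag(D) != 0)) stop("distance matrix must have zero diagonal")
  if (is.null(rownames(D))) dimnames(D) <- list(seq_len(nrow(D)),
                                                seq_len(nrow(D)))
  D
}

#' Distance matrix from a similarity matrix
#'
#' d = 1 - s elementwise.
#'
#' @param S a [SimilarityMatrix] (or symmetric numeric matrix with unit
#'   diagonal).
#' @return symmetric distance matrix with zero diagonal and the ids as
#'   dimnames.
#' @export
distanceFromSimilarity <- function(S) {
  v <- if (is(S, "SimilarityMatrix")) simValues(S) else S
  if (max(abs(v - t(v))) > 1e-8) stop("similarity matrix must be symmetric")
  d <- 1 - v
  diag(d) <- 0
  d
}

.LINKAGES <- c(single = "single", average = "average", complete = "complete",
               ward.d2 = "ward.D2")

#' Hierarchical clustering of a distance matrix
#'
#' Lance-Williams agglomeration via \code{stats::hclust} for the four
#' linkages used in additive profiling (\code{single}, \code{average},
#' \code{complete}, \code{ward.d2}; Ward operates on squared distances and
#' reports square-rooted heights).
#'
#' @param D distance matrix (matrix, \code{dist} or [SimilarityMatrix],
#'   which is converted through [distanceFromSimilarity()]).
#' @param linkage one of \code{"single"}, \code{"average"},
#'   \code{"complete"}, \code{"ward.d2"}.
#' @return an \code{hclust} object.
#' @export
hcluster <- function(D, linkage = c("ward.d2", "single", "average",
                                    "complete")) {
  linkage <- match.arg(linkage)
  D <- .asDistanceMatrix(D)
  if (nrow(D) < 2L) stop("need at least two observations")
  stats::hclust(stats::as.dist(D), method = .LINKAGES[[linkage]])
}

#' Cophenetic correlation of a dendrogram
#'
#' Pearson correlation between the original pairwise distances and the
#' cophenetic distances (height of the lowest common cluster); the linkage
#' with the highest value is the one that best preserves the input metric.
#'
#' @param tree an \code{hclust} object built from \code{D}.
#' @param D the distance matrix the tree was built from.
#' @return correlation in [-1, 1].
#' @export
copheneticCorr <- function(tree, D) {
  D <- .asDistanceMatrix(D)
  d0 <- stats::as.dist(D)
  if (stats::sd(d0) == 0) stop("zero-variance distances: cophenetic correlation undefined")
  stats::cor(d0, stats::cophenetic(tree))
}

#' Cut a dendrogram into k clusters
#'
#' Removes the k-1 highest merges; labels are renumbered in first-occurrence
#' order so that labellings are stable across platforms.
#'
#' @param tree an \code{hclust} object.
#' @param k number of clusters, 1 <= k <= n.
#' @return named integer vector of cluster labels.
#' @export
cutK <- function(tree, k) {
  n <- length(tree$order) ; k <- as.integer(k)
  if (k < 1L || k > n) stop("k out of range")
  raw <- stats::cutree(tree, k = k)
  .relabelFirstOccurrence(raw)
}

.relabelFirstOccurrence <- function(labels) {
  map <- integer(0)
  out <- integer(length(labels))
  for (i in seq_along(labels)) {
    key <- as.character(labels[i])
    if (is.null(names(map)) || !key %in% names(map))
      map[key] <- length(map) + 1L
    out[i] <- map[[key]]
  }
  names(out) <- names(labels)
  out
}

#' Binning clustering at fixed distance cutoffs
#'
#' Single-linkage threshold grouping: at each cutoff (a fraction of the
#' maximum pairwise distance) compounds joined by a path of distances
#' below the threshold form one bin. Feature-matrix input is z-score
#' normalized and converted to Euclidean distances first.
#'
#' @param X feature matrix (rows = compounds) or a distance matrix /
#'   [SimilarityMatrix].
#' @param cutoffs numeric vector of cutoff fractions in [0, 1].
#' @return list with one element per cutoff: \code{cutoff},
#'   \code{sizes} (cluster-size multiset, decreasing) and
#'   \code{membership} (named integer vector).
#' @export
binCluster <- function(X, cutoffs = c(0.3, 0.6)) {
  if (!length(cutoffs)) stop("empty cutoff list")
  isDist <- is(X, "SimilarityMatrix") || inherits(X, "dist") ||
    (is.matrix(X) && nrow(X) == ncol(X) &&
       isTRUE(all.equal(unname(X), unname(t(X)))) && all(diag(X) == 0))
  D <- if (isDist) .asDistanceMatrix(X) else .euclideanFromFeatures(as.matrix(X))
  maxd <- max(D)
  tree <- stats::hclust(stats::as.dist(D), method = "single")
  lapply(cutoffs, function(f) {
    h <- f * maxd
    mem <- if (maxd == 0) rep(1L, nrow(D))
    else .relabelFirstOccurrence(stats::cutree(tree, h = h))
    names(mem) <- rownames(D)
    list(cutoff = f,
         sizes = sort(tabulate(mem), decreasing = TRUE),
         membership = mem)
  })
}

.euclideanFromFeatures <- function(X) {
  X <- as.matrix(X)
  sds <- apply(X, 2, stats::sd)
  sds[sds == 0] <- 1
  Z <- scale(X, center = TRUE, scale = sds)
  as.matrix(stats::dist(Z))
}

#' Seeded k-means with k-means++ initialization
#'
#' Lloyd iterations from k-means++ seeding, best of \code{restarts} runs by
#' within-cluster sum of squares. Distance-matrix input is embedded by
#' classical multidimensional scaling (dimension min(n-1, 10)) first.
#'
#' @param X numeric feature matrix, or a distance matrix /
#'   [SimilarityMatrix].
#' @param k number of clusters.
#' @param seed integer seed; the same seed yields identical labels.
#' @param restarts number of k-means++ restarts (default 10).
#' @return named integer vector of cluster labels (first-occurrence order).
#' @export
kmeansCluster <- function(X, k, seed = 1L, restarts = 10L) {
  X <- .numericEmbedding(X)
  n <- nrow(X)
  if (k > n) stop("k exceeds the number of observations")
  if (k == n) {
    labs <- seq_len(n); names(labs) <- rownames(X); return(labs)
  }
  set.seed(as.integer(seed))
  best <- NULL
  for (r in seq_len(restarts)) {
    centers <- .kmeansPP(X, k)
    fit <- suppressWarnings(stats::kmeans(X, centers = centers,
                                          iter.max = 100L,
                                          algorithm = "Lloyd"))
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  labs <- .relabelFirstOccurrence(best$cluster)
  names(labs) <- rownames(X)
  labs
}

## classical MDS embedding for distance input; identity for features
.numericEmbedding <- function(X) {
  if (is(X, "SimilarityMatrix")) X <- distanceFromSimilarity(X)
  if (inherits(X, "dist")) X <- as.matrix(X)
  X <- as.matrix(X)
  isDist <- nrow(X) == ncol(X) && isTRUE(all.equal(unname(X), unname(t(X)))) &&
    all(diag(X) == 0) && all(X >= 0)
  if (isDist && nrow(X) > 2L) {
    k <- min(nrow(X) - 1L, 10L)
    Y <- suppressWarnings(stats::cmdscale(stats::as.dist(X), k = k))
    rownames(Y) <- rownames(X)
    return(Y)
  }
  X
}

.kmeansPP <- function(X, k) {
  n <- nrow(X)
  centers <- numeric(0)
  first <- sample.int(n, 1L)
  idx <- first
  d2 <- rowSums((X - matrix(X[first, ], n, ncol(X), byrow = TRUE))^2)
  while (length(idx) < k) {
    prob <- d2 / sum(d2)
    if (all(!is.finite(prob)) || sum(d2) == 0)
      cand <- sample.int(n, 1L)
    else cand <- sample.int(n, 1L, prob = prob)
    idx <- c(idx, cand)
    nd <- rowSums((X - matrix(X[cand, ], n, ncol(X), byrow = TRUE))^2)
    d2 <- pmin(d2, nd)
  }
  X[idx, , drop = FALSE]
}
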