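## Internal cluster-validity indices (connectivity, Dunn, silhouette),
## column-deletion stability indices (APN, AD, ADM, FOM) and the
## majority-vote choice of k. Definitions follow the clValid conventions;
## implementations are self-contained.

#' Internal cluster-validity indices
#'
#' Connectivity (sum over each point's L nearest neighbors of 1/rank for
#' neighbors outside the point's cluster; lower is better), the Dunn index
#' (minimum inter-cluster distance over maximum cluster diameter; higher is
#' better) and the mean silhouette width (higher is better).
#'
#' @param D distance matrix (matrix, \code{dist} or [SimilarityMatrix]).
#' @param labels integer cluster labels, >= 2 clusters, none empty.
#' @param neighbors L, the neighborhood size for connectivity (default 10).
#' @return named list \code{connectivity}, \code{dunn}, \code{silhouette}.
#' @export
internalIndices <- function(D, labels, neighbors = 10L) {
  D <- .asDistanceMatrix(D)
  n <- nrow(D)
  labels <- as.integer(labels)
  stopifnot(length(labels) == n)
  if (length(unique(labels)) < 2L) stop("need at least two clusters")
  L <- min(neighbors, n - 1L)
  conn <- 0
  for (i in seq_len(n)) {
    ord <- order(D[i, -i])
    nn <- seq_len(n)[-i][ord][seq_len(L)]
    out <- labels[nn] != labels[i]
    conn <- conn + sum(ifelse(out, 1 / seq_len(L), 0))
  }
  list(connectivity = conn,
       dunn = dunnIndex(D, labels),
       silhouette = mean(silhouetteWidths(D, labels)))
}

#' @describeIn internalIndices Dunn index; singleton-only clusterings have
#'   undefined diameter and return 0 with a warning.
#' @export
dunnIndex <- function(D, labels) {
  D <- .asDistanceMatrix(D)
  labels <- as.integer(labels)
  cl <- unique(labels)
  maxDiam <- 0
  for (g in cl) {
    idx <- which(labels == g)
    if (length(idx) > 1L) maxDiam <- max(maxDiam, max(D[idx, idx]))
  }
  if (maxDiam == 0) {
    warning("all clusters are singletons (or zero-diameter); Dunn index set to 0")
    return(0)
  }
  minSep <- Inf
  for (i in seq_along(cl)) for (j in seq_along(cl)) {
    if (i >= j) next
    minSep <- min(minSep, min(D[labels == cl[i], labels == cl[j]]))
  }
  minSep / maxDiam
}

#' @describeIn internalIndices per-point silhouette widths
#'   (b - a) / max(a, b); singletons get 0.
#' @export
silhouetteWidths <- function(D, labels) {
  D <- .asDistanceMatrix(D)
  n <- nrow(D)
  labels <- as.integer(labels)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    if (length(own) == 1L) { s[i] <- 0; next }
    a <- mean(D[i, setdiff(own, i)])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(g)
      mean(D[i, labels == g]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  s
}

#' Column-deletion stability indices (APN, AD, ADM, FOM)
#'
#' For each single-column deletion the data are reclustered and compared to
#' the full-data clustering: APN is the average proportion of observations
#' not assigned to the same cluster; AD the average distance between
#' observations co-clustered under both partitions; ADM the average
#' distance between the centroids of the clusters an observation belongs
#' to; FOM the root-mean intra-cluster variance of the removed column
#' (adjusted by sqrt(n/(n-k))). All four are averaged over columns; lower
#' is better.
#'
#' @param X numeric feature matrix with >= 2 columns (rows = observations).
#' @param k number of clusters.
#' @param method \code{"hclust"} (ward.d2) or \code{"kmeans"}.
#' @param seed seed used for k-means reclustering.
#' @return named list \code{apn}, \code{ad}, \code{adm}, \code{fom}.
#' @export
stabilityIndices <- function(X, k, method = c("hclust", "kmeans"), seed = 1L) {
  method <- match.arg(method)
  X <- as.matrix(X)
  n <- nrow(X); M <- ncol(X)
  if (M < 2L) stop("need at least two feature columns")
  if (k > n) stop("k exceeds the number of observations")
  clusterOf <- function(mat) {
    if (method == "hclust")
      cutK(hcluster(as.matrix(stats::dist(mat)), "ward.d2"), k)
    else kmeansCluster(mat, k, seed = seed)
  }
  full <- clusterOf(X)
  Dfull <- as.matrix(stats::dist(X))
  apn <- ad <- adm <- fom <- 0
  for (l in seq_len(M)) {
    del <- clusterOf(X[, -l, drop = FALSE])
    for (i in seq_len(n)) {
      A <- which(full == full[i])
      B <- which(del == del[i])
      apn <- apn + (1 - length(intersect(A, B)) / length(A))
      ad <- ad + mean(Dfull[A, B])
      adm <- adm + sqrt(sum((colMeans(X[B, , drop = FALSE]) -
                             colMeans(X[A, , drop = FALSE]))^2))
    }
    ## FOM of the removed column under the deleted-data clustering
    sse <- 0
    for (g in unique(del)) {
      idx <- which(del == g)
      sse <- sse + sum((X[idx, l] - mean(X[idx, l]))^2)
    }
    fom <- fom + sqrt(sse / n) * sqrt(n / (n - k))
  }
  list(apn = apn / (n * M), ad = ad / (n * M), adm = adm / (n * M),
       fom = fom / M)
}

#' Majority-vote selection of the number of clusters
#'
#' Each validity measure names its best k (minimum for connectivity, APN,
#' AD, ADM and FOM; maximum for Dunn and silhouette); the candidate set is
#' the k values named by the most measures, ties retained.
#'
#' @param report data.frame with columns \code{measure}, \code{k},
#'   \code{score} (one row per measure/k combination).
#' @return list with \code{votes} (best k per measure) and
#'   \code{candidates} (integer vector).
#' @export
selectK <- function(report) {
  if (!nrow(report)) stop("empty validation report")
  lowerBetter <- c("connectivity", "apn", "ad", "adm", "fom")
  votes <- vapply(split(report, report$measure), function(d) {
    best <- if (tolower(d$measure[1]) %in% lowerBetter)
      which.min(d$score) else which.max(d$score)
    as.integer(d$k[best])
  }, integer(1))
  tab <- table(votes)
  cand <- sort(as.integer(names(tab)[tab == max(tab)]))
  list(votes = votes, candidates = cand)
}

#' Validation report over a k range
#'
#' Scores hierarchical (ward.d2) or k-means clusterings for each k with the
#' three internal and four stability measures, in one tidy table suitable
#' for [selectK()].
#'
#' @param X feature matrix (stability indices need features; a distance
#'   matrix is embedded by classical MDS for clustering but stability is
#'   then computed on the embedding).
#' @param kRange integer vector of cluster numbers (default 2:6).
#' @param method \code{"hclust"} or \code{"kmeans"}.
#' @param neighbors connectivity neighborhood size.
#' @param seed seed for k-means.
#' @return data.frame with columns \code{method}, \code{measure}, \code{k},
#'   \code{score}.
#' @export
validationReport <- function(X, kRange = 2:6, method = c("hclust", "kmeans"),
                             neighbors = 10L, seed = 1L) {
  method <- match.arg(method)
  emb <- .numericEmbedding(X)
  D <- as.matrix(stats::dist(emb))
  rows <- list()
  for (k in kRange) {
    labels <- if (method == "hclust") cutK(hcluster(D, "ward.d2"), k)
    else kmeansCluster(emb, k, seed = seed)
    ii <- internalIndices(D, labels, neighbors)
    si <- stabilityIndices(emb, k, method, seed = seed)
    for (m in c("connectivity", "dunn", "silhouette"))
      rows[[length(rows) + 1L]] <- data.frame(method = method, measure = m,
                                              k = k, score = ii[[m]])
    for (m in c("apn", "ad", "adm", "fom"))
      rows[[length(rows) + 1L]] <- data.frame(method = method, measure = m,
                                              k = k, score = si[[m]])
  }
  do.call(rbind, rows)
}
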