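## Bootstrap assessment of cluster stability: resample observations with
## replacement, recluster the induced sub-distance-matrix, and match each
## original cluster to the bootstrap cluster with the highest Jaccard
## similarity over the resampled universe. The average of those maxima
## (AvgJ) grades each cluster; a resample in which the best Jaccard falls
## below 0.5 "dissolves" the cluster.

#' Bootstrap cluster stability (average Jaccard and dissolution rate)
#'
#' @param D distance matrix (matrix, \code{dist} or [SimilarityMatrix]).
#' @param k number of clusters (>= 2).
#' @param B number of bootstrap resamples (default 100).
#' @param seed integer seed; identical seed and B give an identical report.
#' @param linkage linkage for the hierarchical clusterings.
#' @return data.frame with one row per original cluster: \code{cluster},
#'   \code{size}, \code{avg_jaccard}, \code{dissolution_rate} and
#'   \code{stability} (\code{unstable} < 0.65 <= \code{stable} <= 0.85 <
#'   \code{highly stable}).
#' @export
bootstrapStability <- function(D, k, B = 100L, seed = 1L,
                               linkage = "ward.d2") {
  if (B < 1L) stop("B must be >= 1")
  if (k < 2L) stop("k must be >= 2")
  D <- .asDistanceMatrix(D)
  n <- nrow(D)
  tree <- hcluster(D, linkage)
  orig <- cutK(tree, k)
  set.seed(as.integer(seed))
  jac <- matrix(NA_real_, B, k)
  for (b in seq_len(B)) {
    idx <- sort(sample.int(n, n, replace = TRUE))
    uni <- unique(idx)
    if (length(uni) < 2L) { jac[b, ] <- 0; next }
    sub <- D[idx, idx, drop = FALSE]
    kk <- min(k, length(uni))
    bl <- cutK(stats::hclust(stats::as.dist(sub),
                             method = .LINKAGES[[linkage]]), kk)
    ## map bootstrap labels back to original indices (unique universe)
    bootClusters <- lapply(seq_len(kk), function(g) unique(idx[bl == g]))
    for (g in seq_len(k)) {
      A <- intersect(which(orig == g), uni)
      if (!length(A)) { jac[b, g] <- 0; next }
      jac[b, g] <- max(vapply(bootClusters, function(Bset)
        length(intersect(A, Bset)) / length(union(A, Bset)), numeric(1)))
    }
  }
  avg <- colMeans(jac)
  diss <- colMeans(jac < 0.5)
  data.frame(
    cluster = seq_len(k),
    size = as.integer(tabulate(orig, nbins = k)),
    avg_jaccard = avg,
    dissolution_rate = diss,
    stability = ifelse(avg < 0.65, "unstable",
                       ifelse(avg > 0.85, "highly stable", "stable")),
    stringsAsFactors = FALSE)
}
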