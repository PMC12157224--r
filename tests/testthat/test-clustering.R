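test_that("distanceFromSimilarity complements and validates", {
  S <- .SimilarityMatrix(c("a", "b"), matrix(c(1, 0.76, 0.76, 1), 2))
  D <- distanceFromSimilarity(S)
  expect_equal(D["a", "b"], 0.24)
  expect_equal(unname(diag(D)), c(0, 0))
  bad <- matrix(c(1, 0.2, 0.8, 1), 2)
  expect_error(distanceFromSimilarity(bad), "symmetric")
})

test_that("hierarchical clustering reproduces ultrametrics and MST heights", {
  ## two points merge at their distance
  D2 <- matrix(c(0, 3, 3, 0), 2, dimnames = list(c("x", "y"), c("x", "y")))
  t2 <- hcluster(D2, "single")
  expect_equal(t2$height, 3)
  ## ultrametric 4-point fixed point, all reproducing linkages
  U <- matrix(c(0, 1, 4, 4,
                1, 0, 4, 4,
                4, 4, 0, 2,
                4, 4, 2, 0), 4,
              dimnames = list(letters[1:4], letters[1:4]))
  for (l in c("single", "average", "complete")) {
    tr <- hcluster(U, l)
    expect_equal(sort(tr$height), c(1, 2, 4), label = l)
    expect_equal(copheneticCorr(tr, U), 1, label = l)
  }
  ## single-linkage heights equal MST edge weights; heights monotone
  for (s in 1:20) {
    D <- randomDistanceMatrix(8L, s)
    expect_equal(sort(hcluster(D, "single")$height), mstEdgeWeights(D),
                 label = paste("mst", s))
    for (l in c("single", "average", "complete", "ward.d2"))
      expect_true(!is.unsorted(hcluster(D, l)$height),
                  label = paste(l, s))
  }
  expect_error(hcluster(matrix(0, 1, 1)), "two observations")
})

test_that("cutK spans k = 1..n with stable first-occurrence labels", {
  D <- randomDistanceMatrix(7L, 11)
  tr <- hcluster(D, "ward.d2")
  expect_equal(unname(cutK(tr, 1L)), rep(1L, 7))
  expect_equal(sort(unname(cutK(tr, 7L))), 1:7)
  labs <- cutK(tr, 3L)
  expect_equal(unique(unname(labs)), c(1L, 2L, 3L))  # first-occurrence order
  expect_error(cutK(tr, 0L), "out of range")
  expect_error(cutK(tr, 8L), "out of range")
})

test_that("internal indices match brute-force oracles on all small partitions", {
  ## hand example: collinear points 0, 1, 10, 11 split in the middle
  D <- as.matrix(stats::dist(c(0, 1, 10, 11)))
  labs <- c(1L, 1L, 2L, 2L)
  ii <- internalIndices(D, labs, neighbors = 1L)
  expect_equal(ii$dunn, 9)
  expect_equal(silhouetteWidths(D, labs)[1], (10.5 - 1) / 10.5)
  ## every point's nearest neighbor is its cluster mate: no violations
  expect_equal(ii$connectivity, 0)
  ## exhaustive agreement over every partition of 6 points
  D6 <- randomDistanceMatrix(6L, 21)
  for (part in allPartitions(6L)) {
    if (length(unique(part)) < 2L) next
    expect_equal(dunnIndex(D6, part), oracleDunn(D6, part))
    expect_equal(mean(silhouetteWidths(D6, part)),
                 oracleSilhouette(D6, part))
  }
  ## agreement with cluster::silhouette
  labs6 <- cutK(hcluster(D6, "average"), 3L)
  sw <- cluster::silhouette(labs6, stats::as.dist(D6))
  expect_equal(mean(silhouetteWidths(D6, labs6)), mean(sw[, "sil_width"]))
  ## all-singleton Dunn warns and returns 0
  expect_warning(d0 <- dunnIndex(D6, 1:6), "singleton")
  expect_equal(d0, 0)
})

test_that("binning clustering groups by thresholded single linkage", {
  X <- rbind(matrix(0, 4, 2), matrix(10, 5, 2))
  rownames(X) <- paste0("p", 1:9)
  res <- binCluster(X, cutoffs = 0.3)
  expect_equal(sort(res[[1]]$sizes, decreasing = TRUE), c(5L, 4L))
  ## identical rows collapse at any positive cutoff
  Xd <- matrix(1, 5, 3)
  res2 <- binCluster(Xd, cutoffs = c(0.2, 0.8))
  expect_equal(res2[[1]]$sizes, 5L)
  ## duplicated point set at cutoff 0: duplicate groups
  Xdup <- rbind(c(0, 0), c(0, 0), c(5, 5))
  rownames(Xdup) <- c("a", "b", "c")
  res3 <- binCluster(Xdup, cutoffs = 0)
  expect_equal(sort(res3[[1]]$sizes, decreasing = TRUE), c(2L, 1L))
  expect_error(binCluster(X, numeric(0)), "empty cutoff")
})

test_that("seeded k-means is deterministic and recovers planted clusters", {
  g <- gaussianFeatureMatrix(5, k = 3L, nPerCluster = 8L, separation = 6)
  l1 <- kmeansCluster(g$X, 3L, seed = 9L)
  l2 <- kmeansCluster(g$X, 3L, seed = 9L)
  expect_identical(l1, l2)
  expect_equal(length(unique(l1)), 3L)
  ## k = n: all singletons
  expect_equal(sort(unname(kmeansCluster(g$X[1:5, ], 5L))), 1:5)
  expect_error(kmeansCluster(g$X, 99L), "exceeds")
  ## recovery across seeds at 6-sigma separation (20 points per cluster,
  ## keeping the 0.9 threshold above the single-misassignment score)
  hits <- 0L
  for (s in 1:100) {
    g <- gaussianFeatureMatrix(s, k = 3L, nPerCluster = 20L, separation = 6)
    labs <- kmeansCluster(g$X, 3L, seed = s)
    if (mclust::adjustedRandIndex(labs, g$labels) >= 0.9) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

test_that("stability indices respond to redundancy, separation and noise", {
  ## three planted classes whose centers stay separated in every single
  ## coordinate, so deleting any one column keeps them separable
  set.seed(3)
  centers <- rbind(c(0, 0), c(10, 12), c(22, 4))
  truth <- rep(1:3, each = 8L)
  X <- centers[truth, ] + matrix(rnorm(48, sd = 0.3), 24)
  rownames(X) <- sprintf("obs%d", 1:24)
  ## duplicated columns: deletions change nothing
  Xdup <- cbind(X, X)
  si <- stabilityIndices(Xdup, k = 3L)
  expect_equal(si$apn, 0)
  expect_lt(si$adm, 1e-8)
  ## a pure-noise column has higher figure of merit than structure
  ## columns; the noise is kept below the class separation so deleting
  ## any single column leaves the clustering intact
  set.seed(77)
  Xn <- cbind(X, noise = rnorm(nrow(X), sd = 1))
  fomOf <- function(X, l) {
    del <- cutK(hcluster(as.matrix(stats::dist(X[, -l])), "ward.d2"), 3L)
    sse <- sum(vapply(unique(del), function(gr)
      sum((X[del == gr, l] - mean(X[del == gr, l]))^2), numeric(1)))
    sqrt(sse / nrow(X))
  }
  expect_gt(fomOf(Xn, 3), fomOf(Xn, 1))
  expect_error(stabilityIndices(X[, 1, drop = FALSE], 2L), "two feature")
})

test_that("selectK applies the majority principle over measure votes", {
  rep1 <- data.frame(
    measure = rep(c("ad", "apn", "connectivity", "adm", "fom",
                    "silhouette", "dunn"), each = 3),
    k = rep(2:4, 7),
    score = c(1, 2, 3,  1, 2, 3,  1, 2, 3,    # best k = 2 (lower better)
              3, 2, 1,  3, 2, 1,              # adm, fom best k = 4
              1, 2, 3,                        # silhouette best k = 4
              1, 3, 2))                       # dunn best k = 3
  sel <- selectK(rep1)
  expect_equal(sel$candidates, c(2L, 4L))
  expect_equal(unname(sel$votes[["dunn"]]), 3L)
  ## unanimous and fully tied cases
  rep2 <- data.frame(measure = rep(c("ad", "fom"), each = 2),
                     k = rep(2:3, 2), score = c(1, 2, 1, 2))
  expect_equal(selectK(rep2)$candidates, 2L)
  rep3 <- data.frame(measure = c("ad", "dunn"), k = c(2, 2),
                     score = c(1, 1))
  expect_error(selectK(data.frame()), "empty")
})

test_that("bootstrap stability separates tight clusters from noise", {
  ## deterministic under seed
  D <- as.matrix(stats::dist(gaussianFeatureMatrix(8, k = 2L,
                                                   nPerCluster = 6L,
                                                   separation = 8)$X))
  b1 <- bootstrapStability(D, 2L, B = 30L, seed = 4L)
  b2 <- bootstrapStability(D, 2L, B = 30L, seed = 4L)
  expect_identical(b1, b2)
  ## far-apart tight clusters: essentially perfect Jaccard
  expect_true(all(b1$avg_jaccard > 0.95))
  expect_true(all(b1$stability == "highly stable"))
  ## average stability decays as separation shrinks
  avgAt <- function(sep) {
    vals <- vapply(1:5, function(s) {
      X <- gaussianFeatureMatrix(s, k = 3L, nPerCluster = 6L,
                                 separation = sep)$X
      mean(bootstrapStability(as.matrix(stats::dist(X)), 3L, B = 20L,
                              seed = s)$avg_jaccard)
    }, numeric(1))
    mean(vals)
  }
  expect_gt(avgAt(6), avgAt(0))
  expect_error(bootstrapStability(D, 2L, B = 0L), "B must be")
})
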