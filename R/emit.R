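## Table emitters and readers. Similarity matrices are emitted as
## upper-triangle TSVs with sub-cutoff cells blank (study-table layout) and
## as full-precision JSON; dendrograms as Newick text and merge-list JSON.
## Every emitted file is re-parseable by the readers here.

#' Write a similarity matrix as an upper-triangle TSV
#'
#' Cells below the matrix's reporting cutoff are left blank, the diagonal
#' is 1; values are rounded to two decimals (the archival JSON emitter
#' keeps full precision).
#'
#' @param S a [SimilarityMatrix].
#' @param path output path.
#' @param digits rounding for report cells.
#' @export
writeSimilarityTSV <- function(S, path, digits = 2) {
  v <- simValues(S)
  n <- nrow(v)
  cut <- S@cutoff
  rows <- character(n + 1L)
  rows[1] <- paste(c("CID", S@ids), collapse = "\t")
  for (i in seq_len(n)) {
    cells <- character(n)
    for (j in seq_len(n)) {
      cells[j] <- if (j < i) ""
      else if (!is.na(cut) && j > i && v[i, j] < cut) ""
      else format(round(v[i, j], digits), nsmall = digits)
    }
    rows[i + 1L] <- paste(c(S@ids[i], cells), collapse = "\t")
  }
  writeLines(rows, path)
  invisible(path)
}

#' Read an upper-triangle similarity TSV back into a SimilarityMatrix
#'
#' Blank (masked) cells are restored as 0.
#'
#' @param path file written by [writeSimilarityTSV()].
#' @param cutoff cutoff to record on the restored matrix.
#' @return a [SimilarityMatrix].
#' @export
readSimilarityTSV <- function(path, cutoff = NA) {
  lines <- strsplit(readLines(path), "\t")
  ids <- lines[[1]][-1]
  n <- length(ids)
  v <- matrix(0, n, n)
  for (i in seq_len(n)) {
    cells <- lines[[i + 1L]][-1]
    cells <- c(cells, rep("", n - length(cells)))
    for (j in seq_len(n)) {
      x <- suppressWarnings(as.numeric(cells[j]))
      if (!is.na(x)) v[i, j] <- x
    }
  }
  v[lower.tri(v)] <- t(v)[lower.tri(v)]
  diag(v) <- 1
  .SimilarityMatrix(ids, v, cutoff)
}

#' Full-precision JSON emitter for a similarity matrix
#'
#' @param S a [SimilarityMatrix].
#' @param path output path.
#' @export
writeSimilarityJSON <- function(S, path) {
  jsonlite::write_json(list(ids = S@ids, cutoff = S@cutoff,
                            values = simValues(S)),
                       path, digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  invisible(path)
}

#' Newick serialization of an hclust dendrogram
#'
#' @param tree an \code{hclust} object with \code{labels}.
#' @return single Newick string with branch lengths derived from merge
#'   heights.
#' @export
dendrogramNewick <- function(tree) {
  lab <- tree$labels
  if (is.null(lab)) lab <- as.character(seq_len(length(tree$order)))
  node <- function(i, parentH) {
    if (i < 0) sprintf("%s:%.10g", lab[-i], parentH)
    else sprintf("(%s,%s):%.10g",
                 node(tree$merge[i, 1], tree$height[i]),
                 node(tree$merge[i, 2], tree$height[i]),
                 parentH - tree$height[i])
  }
  top <- nrow(tree$merge)
  sprintf("(%s,%s);",
          node(tree$merge[top, 1], tree$height[top]),
          node(tree$merge[top, 2], tree$height[top]))
}

#' Heatmap-ordered distance matrix TSV
#'
#' Emits the distance matrix with rows and columns ordered by the
#' dendrogram leaf order, the layout used for a clustered-heatmap figure.
#'
#' @param D distance matrix.
#' @param tree an \code{hclust} object on the same ids.
#' @param path output path.
#' @export
writeHeatmapTSV <- function(D, tree, path) {
  D <- .asDistanceMatrix(D)
  ord <- tree$order
  M <- D[ord, ord]
  utils::write.table(round(M, 4), path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}

#' Per-cluster property summary (min / max / mean / sample sd)
#'
#' @param labels named cluster labels (names = compound ids).
#' @param properties data.frame of numeric property columns with rownames
#'   (or a \code{cid} column) matching the label names.
#' @return data.frame with one row per cluster and statistic.
#' @export
clusterPropertySummary <- function(labels, properties) {
  if ("cid" %in% names(properties)) {
    rownames(properties) <- properties$cid
    properties$cid <- NULL
  }
  ids <- names(labels)
  if (is.null(ids)) stop("labels must be named by compound id")
  missing <- setdiff(ids, rownames(properties))
  if (length(missing))
    stop("no property row for: ", paste(missing, collapse = ", "))
  numCols <- names(properties)[vapply(properties, is.numeric, logical(1))]
  rows <- list()
  for (g in sort(unique(labels))) {
    sub <- properties[ids[labels == g], numCols, drop = FALSE]
    for (stat in c("min", "max", "mean", "sd")) {
      vals <- vapply(numCols, function(cn) {
        x <- sub[[cn]]
        switch(stat, min = min(x), max = max(x), mean = mean(x),
               sd = if (length(x) > 1L) stats::sd(x) else NA_real_)
      }, numeric(1))
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(cluster = g, n = nrow(sub), statistic = stat),
              as.data.frame(as.list(vals)))
    }
  }
  do.call(rbind, rows)
}
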