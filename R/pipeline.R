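## End-to-end orchestration: census and descriptors, similarity matrices,
## clustering with linkage selection, validation, bootstrap stability and
## risk flags, written to an output directory with a manifest and log.

#' Default pipeline configuration
#'
#' @param cutoff atom-pair reporting cutoff (default 0.30).
#' @param au,bu MCS mismatch budgets.
#' @param mcsTimeout per-pair MCS budget, seconds.
#' @param distance which MCS coefficient drives clustering (d = 1 -
#'   coefficient). The default \code{"oc"} reproduces the study-set cluster
#'   memberships; \code{"tc"} is the alternative.
#' @param kRange candidate numbers of clusters.
#' @param bootstrapB bootstrap resamples.
#' @param seed master seed.
#' @return named list understood by [runPipeline()].
#' @export
pipelineConfig <- function(cutoff = 0.30, au = 0L, bu = 0L, mcsTimeout = 5,
                           distance = c("oc", "tc"), kRange = 2:6,
                           bootstrapB = 100L, seed = 42L) {
  list(cutoff = cutoff, au = au, bu = bu, mcsTimeout = mcsTimeout,
       distance = match.arg(distance), kRange = kRange,
       bootstrapB = bootstrapB, seed = seed)
}

#' Run the full additive-profiling pipeline
#'
#' @param mols list of [Molecule] (default: the packaged study set).
#' @param config configuration from [pipelineConfig()].
#' @param outdir optional output directory; when given, all tables are
#'   emitted there together with a JSON manifest.
#' @param verbose log one line per stage.
#' @return report bundle: \code{census}, \code{descriptors}, \code{ap}
#'   ([SimilarityMatrix]), \code{mcs} (oc/tc/exhausted), \code{tree},
#'   \code{copheneticByLinkage}, \code{labels} (per k),
#'   \code{validation}, \code{kCandidates}, \code{bootstrap}, \code{risk}.
#' @export
runPipeline <- function(mols = studyMolecules(), config = pipelineConfig(),
                        outdir = NULL, verbose = TRUE) {
  if (!length(mols)) stop("no input molecules (usage)")
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- Sys.time()
  say("stage census: %d molecules", length(mols))
  census <- censusTable(mols)
  say("stage descriptors")
  desc <- descriptorTable(mols)
  say("stage atom-pair similarity (cutoff %.2f)", config$cutoff)
  ap <- apMatrix(mols, cutoff = config$cutoff)
  say("stage MCS similarity (au=%d bu=%d timeout=%gs)",
      config$au, config$bu, config$mcsTimeout)
  mcsRes <- mcsMatrix(mols, au = config$au, bu = config$bu,
                      timeout = config$mcsTimeout, cutoff = config$cutoff)
  D <- distanceFromSimilarity(mcsRes[[config$distance]])
  say("stage linkage selection")
  coph <- vapply(names(.LINKAGES), function(l)
    copheneticCorr(hcluster(D, l), D), numeric(1))
  bestLinkage <- names(which.max(coph))
  tree <- hcluster(D, bestLinkage)
  say("  best linkage: %s (cophenetic %.4f)", bestLinkage, max(coph))
  labels <- lapply(config$kRange, function(k) cutK(tree, k))
  names(labels) <- as.character(config$kRange)
  say("stage validation (k = %s)", paste(range(config$kRange), collapse = "-"))
  val <- rbind(
    validationReport(D, config$kRange, "hclust", seed = config$seed),
    validationReport(D, config$kRange, "kmeans", seed = config$seed))
  kSel <- selectK(val[val$method == "hclust", ])
  say("stage bootstrap (B = %d)", config$bootstrapB)
  boots <- lapply(kSel$candidates, function(k)
    bootstrapStability(D, k, B = config$bootstrapB, seed = config$seed,
                       linkage = bestLinkage))
  names(boots) <- as.character(kSel$candidates)
  say("stage risk flags")
  risk <- riskTable(desc)
  bundle <- list(census = census, descriptors = desc, ap = ap,
                 mcs = mcsRes, distance = D,
                 copheneticByLinkage = coph, linkage = bestLinkage,
                 tree = tree, labels = labels, validation = val,
                 kCandidates = kSel$candidates, kVotes = kSel$votes,
                 bootstrap = boots, risk = risk,
                 config = config)
  if (!is.null(outdir)) emitBundle(bundle, outdir)
  say("pipeline complete in %.1fs", as.numeric(Sys.time() - t0, units = "secs"))
  bundle
}

#' Write a pipeline bundle to disk
#'
#' Emits census/descriptor/validation/risk TSVs, similarity TSV + JSON
#' mirrors, a Newick dendrogram, a heatmap-ordered matrix and a manifest.
#'
#' @param bundle result of [runPipeline()].
#' @param outdir output directory (created if needed).
#' @return invisibly, the manifest as a list.
#' @export
emitBundle <- function(bundle, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outdir, f)
  wtsv <- function(df, f) utils::write.table(
    df, p(f), sep = "\t", quote = FALSE, row.names = FALSE)
  wtsv(within(bundle$census, mw <- round(mw, 2)), "census.tsv")
  desc <- bundle$descriptors
  for (cn in c("logp", "mr", "tpsa"))
    if (cn %in% names(desc)) desc[[cn]] <- round(desc[[cn]], 4)
  wtsv(desc, "descriptors.tsv")
  writeSimilarityTSV(bundle$ap, p("ap_tanimoto.tsv"))
  writeSimilarityJSON(bundle$ap, p("ap_tanimoto.json"))
  writeSimilarityTSV(bundle$mcs$oc, p("mcs_oc.tsv"))
  writeSimilarityTSV(bundle$mcs$tc, p("mcs_tc.tsv"))
  writeSimilarityJSON(bundle$mcs$tc, p("mcs_tc.json"))
  writeLines(dendrogramNewick(bundle$tree), p("dendrogram.newick"))
  writeHeatmapTSV(bundle$distance, bundle$tree, p("heatmap_matrix.tsv"))
  labs <- do.call(rbind, lapply(names(bundle$labels), function(k)
    data.frame(k = as.integer(k), cid = names(bundle$labels[[k]]),
               cluster = unname(bundle$labels[[k]]))))
  wtsv(labs, "cluster_labels.tsv")
  wtsv(bundle$validation, "validation.tsv")
  for (k in names(bundle$bootstrap))
    wtsv(bundle$bootstrap[[k]], sprintf("bootstrap_k%s.tsv", k))
  risk <- bundle$risk
  for (cn in c("logp", "mr", "tpsa"))
    if (cn %in% names(risk)) risk[[cn]] <- round(risk[[cn]], 4)
  wtsv(risk, "risk.tsv")
  manifest <- list(
    n_molecules = nrow(bundle$census),
    linkage = bundle$linkage,
    cophenetic = as.list(round(bundle$copheneticByLinkage, 6)),
    k_candidates = bundle$kCandidates,
    config = bundle$config,
    files = list.files(outdir))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}
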