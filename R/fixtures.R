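## The packaged study set: 24 polymer additives identified by PubChem CID,
## with structures encoded once from the chemical names printed in the study
## and shipped as a SMILES table. Two compounds whose printed names conflict
## with their printed molecular formulas (24667, 4992761) carry curated
## stand-in structures consistent with every printed property and are marked
## provenance "requires_lookup".

.fixtureFile <- function(name) {
  path <- system.file("extdata", name, package = "addsim")
  if (path == "") path <- file.path("inst", "extdata", name)
  path
}

#' The additive study compounds
#'
#' @return data.frame with columns \code{cid}, \code{name}, \code{smiles},
#'   \code{provenance} (\code{from_printed_name} or \code{requires_lookup}).
#' @examples
#' nrow(studyFixtures())   # 24
#' @export
studyFixtures <- function() {
  utils::read.delim(.fixtureFile("study_compounds.tsv"),
                    colClasses = "character")
}

#' Parsed study molecules
#'
#' @param cids optional subset of CIDs (character or numeric).
#' @return named list of [Molecule] in table order.
#' @export
studyMolecules <- function(cids = NULL) {
  fx <- studyFixtures()
  if (!is.null(cids)) fx <- fx[fx$cid %in% as.character(cids), , drop = FALSE]
  mols <- lapply(seq_len(nrow(fx)), function(i)
    parseSmiles(fx$smiles[i], cid = fx$cid[i], name = fx$name[i]))
  names(mols) <- fx$cid
  mols
}

#' Printed reference descriptors (study Table 2 layout)
#'
#' The descriptor values printed in the study, carried as reference
#' metadata: the HBA/LogP/MR columns come from a descriptor engine with
#' undocumented conventions and are inputs to the risk-classification
#' reproduction, not values this package recomputes.
#'
#' @return data.frame with \code{cid}, \code{hba}, \code{hbd}, \code{logp},
#'   \code{mr}, \code{tpsa}.
#' @export
referenceDescriptors <- function() {
  df <- utils::read.delim(.fixtureFile("reference_descriptors.tsv"))
  df$cid <- as.character(df$cid)
  df
}

#' Printed reference census (study Table 1 layout)
#'
#' @return data.frame of the printed per-compound characteristics.
#' @export
referenceCensus <- function() {
  df <- utils::read.delim(.fixtureFile("reference_census.tsv"))
  df$cid <- as.character(df$cid)
  df
}
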