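## Topological polar surface area by Ertl fragment contributions. Each N, O,
## S or P atom is classified by its local environment (charge, attached
## hydrogens, bond-order multiset, aromaticity, 3-ring membership) and looked
## up in the published contribution table shipped under extdata. S and P
## contributions (Ertl's extended table) are included by default; the
## original N/O-only sum is available with includeSP = FALSE.

.tpsaEnv <- new.env(parent = emptyenv())

.tpsaTable <- function() {
  if (is.null(.tpsaEnv$tab)) {
    path <- system.file("extdata", "tpsa_contributions.tsv", package = "addsim")
    if (path == "") path <- file.path("inst", "extdata", "tpsa_contributions.tsv")
    .tpsaEnv$tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  }
  .tpsaEnv$tab
}

## environment key: element|aromatic|charge|nH|nSingle|nDouble|nTriple|nAromatic|in3ring
.tpsaKey <- function(element, aromatic, charge, nH, s, d, t, ar, ring3) {
  sprintf("%s|%d|%+d|%d|%d|%d|%d|%d|%d", element, as.integer(aromatic),
          charge, nH, s, d, t, ar, as.integer(ring3))
}

#' Topological polar surface area (Ertl fragment sums)
#'
#' @param mol a [Molecule] with hydrogens assigned and aromaticity perceived.
#' @param includeSP include the divalent-S/trivalent-P extended
#'   contributions (default TRUE). With FALSE only N and O environments
#'   contribute, the original TPSA definition.
#' @return TPSA in square Angstrom, full precision (round to 2 decimals for
#'   reporting). Unknown polar environments contribute 0 with a warning.
#' @examples
#' round(tpsa(parseSmiles("CCO")), 2)   # one aliphatic hydroxyl, 20.23
#' @rdname tpsa
#' @export
setMethod("tpsa", "Molecule", function(mol, includeSP = TRUE) {
  a <- mol@atoms; b <- mol@bonds
  polar <- c("N", "O", if (includeSP) c("S", "P"))
  idx <- which(a$element %in% polar)
  if (!length(idx)) return(0)
  tab <- .tpsaTable()
  ## 3-ring membership only differentiates N and O contributions
  ring3 <- logical(nAtoms(mol))
  if (any(a$element[idx] %in% c("N", "O"))) {
    pr <- perceiveRings(mol)
    for (r in pr$rings)
      if (length(r) == 3L)
        ring3[r[a$element[r] %in% c("N", "O")]] <- TRUE
  }
  total <- 0
  for (v in idx) {
    inc <- which(b$a1 == v | b$a2 == v)
    ords <- b$order[inc]
    key <- .tpsaKey(a$element[v], a$aromatic[v], a$charge[v], a$hcount[v],
                    sum(ords == "single"), sum(ords == "double"),
                    sum(ords == "triple"), sum(ords == "aromatic"), ring3[v])
    hit <- tab$contribution[tab$key == key]
    if (length(hit)) total <- total + hit[1]
    else warning("no TPSA contribution for environment ", key,
                 " (atom ", v, "); contributing 0", call. = FALSE)
  }
  total
})
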