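## Hydrogen-bond donor/acceptor counts and the per-compound descriptor table.

#' Hydrogen-bond donor count
#'
#' Number of oxygen or nitrogen atoms bearing at least one hydrogen (each
#' donor group counted once), so the count is bounded by the number of
#' N + O atoms.
#'
#' @param mol a [Molecule]
#' @return integer count.
#' @rdname countHBD
#' @export
setMethod("countHBD", "Molecule", function(mol) {
  a <- mol@atoms
  as.integer(sum(a$element %in% c("N", "O") & a$hcount > 0L))
})

#' Hydrogen-bond acceptor count (Lipinski-style N + O)
#'
#' Counts nitrogen and oxygen atoms, excluding pyrrole-type aromatic
#' nitrogens (three ring-plane bonds or an aromatic N-H, whose lone pair is
#' part of the pi system) and amide N-H nitrogens. This is the package's
#' primary convention; the descriptor table also carries the study's printed
#' HBA values as reference metadata, which follow a different, undocumented
#' convention and are not reproduced.
#'
#' @param mol a [Molecule]
#' @return integer count.
#' @rdname countHBA
#' @export
setMethod("countHBA", "Molecule", function(mol) {
  a <- mol@atoms; b <- mol@bonds
  cnt <- sum(a$element == "O")
  for (v in which(a$element == "N")) {
    inc <- which(b$a1 == v | b$a2 == v)
    if (a$aromatic[v] && (length(inc) >= 3L || a$hcount[v] > 0L)) next
    if (a$hcount[v] > 0L) {
      ns <- ifelse(b$a1[inc] == v, b$a2[inc], b$a1[inc])
      amide <- any(vapply(ns, function(w) {
        winc <- which(b$a1 == w | b$a2 == w)
        us <- ifelse(b$a1[winc] == w, b$a2[winc], b$a1[winc])
        a$element[w] == "C" &&
          any(a$element[us] == "O" & b$order[winc] == "double")
      }, logical(1)))
      if (amide) next
    }
    cnt <- cnt + 1L
  }
  as.integer(cnt)
})

#' Descriptor table for a set of molecules
#'
#' One row per molecule with HBA, HBD, LogP, MR and TPSA in study-table
#' layout. When the molecules carry CIDs present in the packaged study set,
#' the printed reference descriptor values are attached as \code{ref.*}
#' columns (reference metadata only).
#'
#' @param mols list of [Molecule]
#' @param attachReference attach printed reference columns when available.
#' @return data.frame with columns \code{cid}, \code{hba}, \code{hbd},
#'   \code{logp}, \code{mr}, \code{tpsa} (full precision; round at
#'   serialization).
#' @export
descriptorTable <- function(mols, attachReference = TRUE) {
  if (is(mols, "Molecule")) mols <- list(mols)
  if (!length(mols))
    return(data.frame(cid = character(), hba = integer(), hbd = integer(),
                      logp = numeric(), mr = numeric(), tpsa = numeric()))
  rows <- lapply(mols, function(m) {
    cl <- crippenLogP(m)
    data.frame(cid = m@cid, hba = countHBA(m), hbd = countHBD(m),
               logp = cl$logp, mr = cl$mr, tpsa = tpsa(m),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (attachReference && nrow(df)) {
    ref <- tryCatch(referenceDescriptors(), error = function(e) NULL)
    if (!is.null(ref) && any(df$cid %in% ref$cid)) {
      i <- match(df$cid, ref$cid)
      for (col in c("hba", "hbd", "logp", "mr", "tpsa"))
        df[[paste0("ref.", col)]] <- ref[[col]][i]
    }
  }
  df
}
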