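## Wildman-Crippen additive LogP and molar refractivity. Atom typing is a
## condensed graph-pattern reimplementation of the published atomic
## contribution scheme, covering the environments that occur in polymer
## additives (and in the synthetic generators); contribution values are the
## published ones for those types, shipped as a plain-text table. Atoms in
## environments outside the table contribute 0 with a warning.

.crippenEnv <- new.env(parent = emptyenv())

.crippenTable <- function() {
  if (is.null(.crippenEnv$tab)) {
    path <- system.file("extdata", "crippen_contributions.tsv",
                        package = "addsim")
    if (path == "") path <- file.path("inst", "extdata",
                                      "crippen_contributions.tsv")
    .crippenEnv$tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  }
  .crippenEnv$tab
}

.HETERO <- c("N", "O", "P", "S", "F", "Cl", "Br", "I")

## assign a Crippen type to every atom (heavy atoms; implicit H typed per H)
.crippenTypes <- function(mol) {
  a <- mol@atoms; b <- mol@bonds
  n <- nAtoms(mol)
  nbrOf <- .adjacency(mol)
  bondOrd <- function(v, w) {
    i <- which((b$a1 == v & b$a2 == w) | (b$a1 == w & b$a2 == v))
    b$order[i[1]]
  }
  types <- character(n)
  for (v in seq_len(n)) {
    el <- a$element[v]
    ns <- nbrOf[[v]]
    nel <- a$element[ns]
    narom <- a$aromatic[ns]
    ords <- vapply(ns, function(w) bondOrd(v, w), character(1))
    types[v] <- if (el == "C" && !a$aromatic[v]) {
      if (any(ords %in% c("double", "triple") & nel %in% .HETERO))
        "C.hetdouble"
      else if (any(ords == "double")) {
        if (any(narom)) "C.sp2.ar" else "C.sp2"
      } else if (any(ords == "triple")) "C.sp"
      else if (any(narom) && a$hcount[v] <= 1L)
        paste0("C.sp3.ar.h", a$hcount[v])   # aryl attachment outranks het
      else if (any(nel %in% .HETERO)) {
        if (a$hcount[v] >= 2L) "C.sp3.het.hi" else "C.sp3.het.lo"
      } else if (any(narom)) {
        paste0("C.sp3.ar.h", min(a$hcount[v], 3L))
      } else if (a$hcount[v] >= 2L) "C.sp3.hi" else "C.sp3.lo"
    } else if (el == "C") {                 # aromatic carbon
      aromBonds <- sum(ords == "aromatic")
      sub <- which(ords != "aromatic")
      if (aromBonds >= 3L) "c.fused"
      else if (!length(sub)) "c.h"
      else {
        w <- sub[1]
        if (nel[w] == "O") "c.oxy"
        else if (nel[w] == "N" && !narom[w]) "c.amine"
        else if (narom[w]) "c.arsub"
        else if (nel[w] %in% c("F", "Cl", "Br", "I")) "c.halo"
        else "c.alkyl"
      }
    } else if (el == "N") {
      if (a$aromatic[v]) "n.aromatic"
      else if (a$charge[v] != 0L) "N.unknown"
      else {
        ar <- any(narom)
        deg <- length(ns)
        if (deg >= 3L) paste0("N.tertiary", if (ar) ".ar" else "")
        else if (deg == 2L) paste0("N.secondary", if (ar) ".ar" else "")
        else paste0("N.primary", if (ar) ".ar" else "")
      }
    } else if (el == "O") {
      if (a$aromatic[v]) "o.aromatic"
      else if (a$charge[v] < 0L) "O.carboxylate"
      else if (any(ords == "double")) {
        cc <- ns[ords == "double"][1]
        ccn <- nbrOf[[cc]]
        if (any(a$aromatic[ccn])) "O.carbonyl.ar" else "O.carbonyl"
      } else if (a$hcount[v] > 0L) "O.hydroxyl"
      else if (any(narom)) "O.ether.ar"
      else "O.ether"
    } else if (el == "S") "S.thio"
    else if (el == "P") "P.trivalent"
    else if (el %in% c("F", "Cl", "Br", "I")) el
    else if (el == "Zn") "Zn.ion"
    else paste0(el, ".unknown")
  }
  types
}

#' Wildman-Crippen LogP and molar refractivity
#'
#' Additive atomic-contribution estimates of the octanol/water partition
#' coefficient (LogP, dimensionless) and molar refractivity (MR, cm3/mol).
#' Implicit hydrogens contribute through their attached-heavy-atom class
#' (C-H, N-H, alcohol vs acid O-H).
#'
#' @param mol a [Molecule] with hydrogens and aromaticity assigned.
#' @return named list with \code{logp} and \code{mr}.
#' @examples
#' crippenLogP(parseSmiles("c1ccccc1"))   # 6 x (aromatic CH + H)
#' @rdname crippenLogP
#' @export
setMethod("crippenLogP", "Molecule", function(mol) {
  tab <- .crippenTable()
  types <- .crippenTypes(mol)
  a <- mol@atoms
  logp <- 0; mr <- 0
  for (v in seq_len(nAtoms(mol))) {
    row <- tab[tab$type == types[v], ]
    if (!nrow(row)) {
      warning("no LogP/MR contribution for atom type ", types[v],
              " (atom ", v, "); contributing 0", call. = FALSE)
      next
    }
    logp <- logp + row$logp; mr <- mr + row$mr
    nh <- a$hcount[v]
    if (nh > 0L) {
      htype <- if (a$element[v] == "O") {
        acyl <- .isAcidOxygen(mol, v)
        if (acyl) "H.o.acid" else "H.o"
      } else if (a$element[v] == "N") "H.n" else "H.c"
      hrow <- tab[tab$type == htype, ]
      logp <- logp + nh * hrow$logp; mr <- mr + nh * hrow$mr
    }
  }
  list(logp = logp, mr = mr)
})

## is atom v a hydroxyl O on a carboxylic-acid carbon?
.isAcidOxygen <- function(mol, v) {
  a <- mol@atoms; b <- mol@bonds
  inc <- which(b$a1 == v | b$a2 == v)
  for (i in inc) {
    w <- if (b$a1[i] == v) b$a2[i] else b$a1[i]
    if (a$element[w] != "C") next
    winc <- which(b$a1 == w | b$a2 == w)
    for (j in winc) {
      u <- if (b$a1[j] == w) b$a2[j] else b$a1[j]
      if (u != v && a$element[u] == "O" && b$order[j] == "double") return(TRUE)
    }
  }
  FALSE
}
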