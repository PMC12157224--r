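## SDF V2000 input/output. Aromatic bonds are written with bond type 4, so a
## write/parse round trip preserves aromatic perception without
## kekulization. Charges are carried in "M  CHG" property lines (the charge
## column of the atom block is ignored, as in current V2000 practice).
## Coordinates are read but discarded: the toolkit is purely topological.

#' Parse SDF V2000 records
#'
#' @param input path to an SDF file, or a character vector of lines.
#' @return list of [Molecule], one per record. The record name is used as
#'   the CID when it is numeric.
#' @export
parseSDF <- function(input) {
  lines <- if (length(input) == 1L && !grepl("\n", input) &&
               file.exists(input))
    readLines(input, warn = FALSE)
  else unlist(lapply(input, function(x)     # split embedded newlines only;
    if (grepl("\n", x, fixed = TRUE))       # strsplit would drop "" lines
      strsplit(x, "\n", fixed = TRUE)[[1]] else x))
  ## split records on $$$$
  recEnds <- grep("^\\$\\$\\$\\$\\s*$", lines)
  if (!length(recEnds)) recEnds <- length(lines)
  starts <- c(1L, head(recEnds, -1L) + 1L)
  mols <- vector("list", length(starts))
  for (r in seq_along(starts)) {
    rec <- lines[starts[r]:recEnds[r]]
    rec <- rec[!grepl("^\\$\\$\\$\\$", rec)]
    mols[[r]] <- tryCatch(.parseSDFRecord(rec),
                          error = function(e)
                            stop("SDF record ", r, ": ", conditionMessage(e),
                                 call. = FALSE))
  }
  mols
}

.parseSDFRecord <- function(rec) {
  if (length(rec) < 4L) stop("truncated record")
  name <- trimws(rec[1])
  counts <- rec[4]
  natom <- suppressWarnings(as.integer(substr(counts, 1L, 3L)))
  nbond <- suppressWarnings(as.integer(substr(counts, 4L, 6L)))
  if (is.na(natom) || is.na(nbond)) stop("malformed counts line")
  if (length(rec) < 4L + natom + nbond) stop("record shorter than counts line")
  el <- character(natom)
  for (i in seq_len(natom)) {
    ln <- rec[4L + i]
    el[i] <- trimws(substr(ln, 32L, 34L))
    if (!el[i] %in% .supportedElements())
      stop("unsupported element '", el[i], "' at atom ", i)
  }
  b1 <- integer(nbond); b2 <- integer(nbond); btype <- integer(nbond)
  for (i in seq_len(nbond)) {
    ln <- rec[4L + natom + i]
    b1[i] <- as.integer(substr(ln, 1L, 3L))
    b2[i] <- as.integer(substr(ln, 4L, 6L))
    btype[i] <- as.integer(substr(ln, 7L, 9L))
    if (is.na(b1[i]) || is.na(b2[i]) || b1[i] < 1L || b2[i] < 1L ||
        b1[i] > natom || b2[i] > natom)
      stop("bond ", i, " references atom out of range")
  }
  charge <- integer(natom)
  for (ln in grep("^M  CHG", rec, value = TRUE)) {
    k <- as.integer(substr(ln, 7L, 9L))
    for (j in seq_len(k)) {
      off <- 10L + (j - 1L) * 8L
      idx <- as.integer(substr(ln, off, off + 3L))
      val <- as.integer(substr(ln, off + 4L, off + 7L))
      if (is.na(idx) || idx < 1L || idx > natom)
        stop("M CHG atom index out of range")
      charge[idx] <- val
    }
  }
  ord <- c("single", "double", "triple", "aromatic")[btype]
  if (anyNA(ord)) stop("unsupported bond type")
  aromatic <- logical(natom)
  aromatic[c(b1[ord == "aromatic"], b2[ord == "aromatic"])] <- TRUE
  ## explicit hydrogens in the atom block are folded into heavy-atom hcounts
  isH <- el == "H"
  cid <- if (grepl("^[0-9]+$", name)) name else NA_character_
  mol <- .Molecule(
    atoms = list(element = el, charge = charge, hcount = integer(natom),
                 aromatic = aromatic),
    bonds = list(a1 = b1, a2 = b2, order = ord),
    cid = cid, name = if (nzchar(name)) name else NA_character_)
  mol@atoms$hcount <- .assignImplicitH(mol)
  if (any(isH)) mol <- .foldExplicitH(mol)
  .checkValences(mol)
  mol
}

## Merge explicit H atoms into the hcount of their heavy neighbor.
.foldExplicitH <- function(mol) {
  a <- mol@atoms; b <- mol@bonds
  isH <- a$element == "H" & a$charge == 0L
  if (!any(isH)) return(mol)
  keep <- which(!isH)
  remap <- integer(nrow(a)); remap[keep] <- seq_along(keep)
  extra <- integer(length(keep))
  drop <- logical(nrow(b))
  for (i in seq_len(nrow(b))) {
    h <- if (isH[b$a1[i]]) b$a1[i] else if (isH[b$a2[i]]) b$a2[i] else NA
    if (!is.na(h)) {
      heavy <- if (h == b$a1[i]) b$a2[i] else b$a1[i]
      if (!isH[heavy]) extra[remap[heavy]] <- extra[remap[heavy]] + 1L
      drop[i] <- TRUE
    }
  }
  b <- b[!drop, , drop = FALSE]
  a <- a[keep, , drop = FALSE]
  a$hcount <- a$hcount + extra
  .Molecule(atoms = a,
            bonds = list(a1 = remap[b$a1], a2 = remap[b$a2], order = b$order),
            cid = mol@cid, name = mol@name)
}

#' Write molecules as SDF V2000
#'
#' @param mols list of [Molecule] (a single Molecule is accepted).
#' @param path output file path, or \code{NULL} to return the lines.
#' @return invisibly, the character vector written.
#' @export
writeSDF <- function(mols, path = NULL) {
  if (is(mols, "Molecule")) mols <- list(mols)
  out <- as.character(unlist(lapply(mols, .sdfRecord)))
  if (!is.null(path)) writeLines(out, path)
  invisible(out)
}

.sdfRecord <- function(mol) {
  a <- mol@atoms; b <- mol@bonds
  if (nrow(a) && !all(a$element %in% names(.ATOMIC_WEIGHTS)))
    stop("element without mass entry")
  name <- if (!is.na(mol@cid)) mol@cid else if (!is.na(mol@name)) mol@name else ""
  hdr <- c(name, "  addsim", "", sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                                         nrow(a), nrow(b)))
  atomLines <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                       0, 0, 0, a$element)
  ordNum <- c(single = 1L, double = 2L, triple = 3L, aromatic = 4L)[b$order]
  bondLines <- sprintf("%3d%3d%3d  0", b$a1, b$a2, ordNum)
  chgIdx <- which(a$charge != 0L)
  chgLines <- character()
  while (length(chgIdx)) {
    take <- head(chgIdx, 8L)
    chgIdx <- chgIdx[-seq_along(take)]
    chgLines <- c(chgLines,
                  paste0(sprintf("M  CHG%3d", length(take)),
                         paste(sprintf("%4d%4d", take, a$charge[take]),
                               collapse = "")))
  }
  c(hdr, atomLines, bondLines, chgLines, "M  END", "$$$$")
}
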