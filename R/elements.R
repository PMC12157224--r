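## Element data for the supported chemistry: the organic subset plus the
## heteroatoms occurring in polymer additives (P, S, Cl, Zn, halogens).

## Conventional atomic weights, IUPAC 2005 table (the vintage consistent with
## 2D-structure databases of that era; e.g. Zn 65.409).
.ATOMIC_WEIGHTS <- c(
  H = 1.00794, B = 10.811, C = 12.0107, N = 14.0067, O = 15.9994,
  F = 18.9984032, P = 30.973762, S = 32.065, Cl = 35.453, Br = 79.904,
  I = 126.90447, Zn = 65.409
)

## Allowed total valences (explicit bond order sum + implicit H), neutral atom.
.ALLOWED_VALENCES <- list(
  H = 1L, B = 3L, C = 4L, N = c(3L, 5L), O = 2L, F = 1L,
  P = c(3L, 5L), S = c(2L, 4L, 6L), Cl = 1L, Br = 1L, I = 1L,
  Zn = c(0L, 2L)
)

## Default valence used to assign implicit hydrogens (lowest allowed).
.DEFAULT_VALENCE <- c(
  H = 1L, B = 3L, C = 4L, N = 3L, O = 2L, F = 1L, P = 3L, S = 2L,
  Cl = 1L, Br = 1L, I = 1L, Zn = 0L
)

.METALS <- "Zn"

.supportedElements <- function() names(.ATOMIC_WEIGHTS)

## Charge-adjusted valence target: [N+] 4, [O-] 1, [C-] 3, ...
.valenceTarget <- function(element, charge = 0L) {
  base <- .DEFAULT_VALENCE[[element]]
  if (element %in% c("N", "O", "P", "S", "B")) {
    max(0L, base + as.integer(charge))
  } else if (element == "C") {
    max(0L, base - abs(as.integer(charge)))
  } else {
    base
  }
}

.allowedValences <- function(element, charge = 0L) {
  vals <- .ALLOWED_VALENCES[[element]]
  if (charge != 0L && element %in% c("N", "O", "P", "S", "C", "B")) {
    vals <- unique(pmax(0L, vals + if (element == "C") -abs(charge) else charge))
  }
  vals
}

## Hill-order sort of element symbols: C, H, then alphabetical.
.hillOrder <- function(elements) {
  rest <- sort(setdiff(elements, c("C", "H")))
  c(intersect(c("C", "H"), elements), rest)
}

.BOND_ORDERS <- c(single = 1, double = 2, triple = 3, aromatic = 1.5)

.bondOrderValue <- function(order) unname(.BOND_ORDERS[order])
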