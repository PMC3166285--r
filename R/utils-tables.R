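## Shared residue-level lookup tables.

#' Three-letter to one-letter residue code
#'
#' Maps the 20 standard residues; anything else (modified residues, ligands)
#' maps to \code{"X"}.  Non-standard residues are excluded from class-based
#' scoring but retained for geometry.
#'
#' @param resid character vector of 3-letter residue codes.
#' @return character vector of 1-letter codes.
#' @export
aaThreeToOne <- function(resid) {
  out <- .AA_321[toupper(resid)]
  out[is.na(out)] <- "X"
  unname(out)
}

.AA_321 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

.AA_123 <- structure(names(.AA_321), names = unname(.AA_321))

#' One-letter to three-letter residue code
#' @param aa1 character vector of 1-letter codes; unknown letters map to UNK.
#' @return character vector of 3-letter codes.
#' @export
aaOneToThree <- function(aa1) {
  out <- .AA_123[toupper(aa1)]
  out[is.na(out)] <- "UNK"
  unname(out)
}

.STANDARD_AA <- unname(.AA_321)

## Van der Waals radii (Angstrom) by element; used by the SASA routine.
.VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, D = 1.20,
                P = 1.80, SE = 1.90, ZN = 1.39, FE = 1.47, MG = 1.73)
.VDW_DEFAULT <- 1.70

vdwRadius <- function(element) {
  r <- .VDW_RADII[toupper(element)]
  r[is.na(r)] <- .VDW_DEFAULT
  unname(r)
}

## Theoretical per-residue maximum accessible surface areas (Angstrom^2),
## Tien et al. (2013) theoretical values; denominator for relative SASA.
.MAX_SASA <- c(
  A = 129.0, R = 274.0, N = 195.0, D = 193.0, C = 167.0,
  Q = 225.0, E = 223.0, G = 104.0, H = 224.0, I = 197.0,
  L = 201.0, K = 236.0, M = 224.0, F = 240.0, P = 159.0,
  S = 155.0, T = 172.0, W = 285.0, Y = 263.0, V = 174.0)

#' Maximum accessible surface area reference
#'
#' Per-residue theoretical maximum SASA used as the denominator of relative
#' solvent accessibility.
#'
#' @param aa1 optional character vector of 1-letter codes; when missing the
#'   whole table is returned.
#' @return named numeric vector (Angstrom^2); \code{NA} for unknown letters.
#' @export
maxSasaReference <- function(aa1) {
  if (missing(aa1)) return(.MAX_SASA)
  unname(.MAX_SASA[toupper(aa1)])
}

## Derive an element symbol from a PDB atom name when the element column is
## absent (e.g. minimal files): strip digits, take the first letter, special-
## casing two-letter elements that appear in protein files.
elementFromAtomName <- function(elety) {
  nm <- toupper(gsub("[0-9']", "", elety))
  el <- substr(nm, 1L, 1L)
  el[nm %in% c("SE", "ZN", "FE", "MG")] <- nm[nm %in% c("SE", "ZN", "FE", "MG")]
  el
}

`%||%` <- function(a, b) if (is.null(a)) b else a
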