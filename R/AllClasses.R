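#' @import methods
NULL

#' ProteinStructure: a parsed coordinate hierarchy
#'
#' Holds the atom table of one model of a PDB-format coordinate file after
#' altloc resolution and water removal.  Residue identity is the triple
#' (chain, residue number, insertion code); residues keep their file order.
#'
#' @slot id character label (e.g. PDB code plus chain spec).
#' @slot modelIndex which MODEL block was read (1-based).
#' @slot atoms data.frame with columns \code{chain}, \code{resno},
#'   \code{insert}, \code{resid} (3-letter), \code{aa1}, \code{elety} (atom
#'   name), \code{element}, \code{x}, \code{y}, \code{z}, \code{occ},
#'   \code{altloc}, \code{isHeavy}.
#' @export
setClass("ProteinStructure",
  representation(id = "character", modelIndex = "numeric", atoms = "data.frame"))

setValidity("ProteinStructure", function(object) {
  a <- object@atoms
  need <- c("chain", "resno", "insert", "resid", "aa1", "elety", "element",
            "x", "y", "z", "occ", "altloc", "isHeavy")
  if (!all(need %in% names(a)))
    return(paste("atoms is missing columns:",
                 paste(setdiff(need, names(a)), collapse = ", ")))
  if (nrow(a) == 0L) return("structure has no atoms")
  if (!all(is.finite(a$x) & is.finite(a$y) & is.finite(a$z)))
    return("non-finite coordinates")
  if (any(a$occ < 0 | a$occ > 1, na.rm = TRUE))
    return("occupancy outside [0, 1]")
  key <- paste(a$chain, a$resno, a$insert, a$elety, sep = "\r")
  if (anyDuplicated(key))
    return("duplicate atom (chain, resno, insert, atom-name) after altloc resolution")
  TRUE
})

#' MsAlignment: a gapped multiple sequence alignment
#'
#' Equal-length gapped rows (\code{'-'} gap) with unique ids.  Columns are
#' 1-based; degapping a row recovers its plain sequence.
#'
#' @slot rowIds character vector of record ids (unique, ordered).
#' @slot rows character vector of equal-length gapped strings.
#' @export
setClass("MsAlignment",
  representation(rowIds = "character", rows = "character"))

setValidity("MsAlignment", function(object) {
  if (length(object@rowIds) != length(object@rows))
    return("rowIds and rows differ in length")
  if (length(object@rows) == 0L) return("alignment has no rows")
  if (anyDuplicated(object@rowIds)) return("duplicate row ids")
  if (length(unique(nchar(object@rows))) != 1L)
    return("ragged rows: all rows must have equal length")
  TRUE
})

#' Superposition: a rigid-body fit
#'
#' @slot rotation 3x3 proper rotation matrix (det +1).
#' @slot translation length-3 numeric, Angstrom.
#' @slot rmsd post-fit root-mean-square deviation, Angstrom.
#' @export
setClass("Superposition",
  representation(rotation = "matrix", translation = "numeric", rmsd = "numeric"))

setValidity("Superposition", function(object) {
  R <- object@rotation
  if (!all(dim(R) == c(3L, 3L))) return("rotation must be 3x3")
  if (max(abs(crossprod(R) - diag(3))) > 1e-8) return("rotation not orthonormal")
  if (abs(det(R) - 1) > 1e-8) return("rotation must have determinant +1")
  if (length(object@translation) != 3L) return("translation must have length 3")
  if (object@rmsd < 0) return("rmsd must be non-negative")
  TRUE
})

#' ColumnRmsdProfile: per-column C-alpha spread of a superposed ensemble
#'
#' @slot rmsd numeric per alignment column: RMSD of the equivalent C-alpha
#'   atoms from their centroid, \code{NA} for gap columns.
#' @slot hasGap logical per column.
#' @slot nStructures number of structures contributing.
#' @export
setClass("ColumnRmsdProfile",
  representation(rmsd = "numeric", hasGap = "logical", nStructures = "integer"))

setValidity("ColumnRmsdProfile", function(object) {
  if (length(object@rmsd) != length(object@hasGap))
    return("rmsd and hasGap differ in length")
  if (any(!is.na(object@rmsd) & object@rmsd < 0)) return("negative rmsd")
  if (any(object@hasGap & !is.na(object@rmsd)))
    return("rmsd must be undefined for gap columns")
  TRUE
})

setMethod("show", "ProteinStructure", function(object) {
  rt <- residueTable(object)
  cat(sprintf("ProteinStructure '%s' (model %d): %d atoms, %d residues, chains %s\n",
              object@id, as.integer(object@modelIndex), nrow(object@atoms),
              nrow(rt), paste(unique(object@atoms$chain), collapse = ",")))
})

setMethod("show", "MsAlignment", function(object) {
  cat(sprintf("MsAlignment: %d rows x %d columns\n",
              length(object@rows), nchar(object@rows[1L])))
  ids <- object@rowIds
  if (length(ids) > 6L) ids <- c(ids[1:6], "...")
  cat("  rows:", paste(ids, collapse = " "), "\n")
})

setMethod("show", "Superposition", function(object) {
  cat(sprintf("Superposition: rmsd = %.4f Angstrom\n", object@rmsd))
})

setMethod("show", "ColumnRmsdProfile", function(object) {
  ok <- !is.na(object@rmsd)
  cat(sprintf("ColumnRmsdProfile: %d columns (%d gap-free), %d structures\n",
              length(object@rmsd), sum(ok), object@nStructures))
  if (any(ok))
    cat(sprintf("  rmsd range %.3f - %.3f Angstrom\n",
                min(object@rmsd[ok]), max(object@rmsd[ok])))
})
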