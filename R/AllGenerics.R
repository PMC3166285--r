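#' Atom table accessor
#' @param x a \linkS4class{ProteinStructure}.
#' @return data.frame of atoms.
#' @export
setGeneric("atomTable", function(x) standardGeneric("atomTable"))

#' Residue table accessor
#'
#' One row per residue in file order, with a global 1-based \code{resIndex}.
#' @param x a \linkS4class{ProteinStructure}.
#' @return data.frame with columns resIndex, chain, resno, insert, resid, aa1.
#' @export
setGeneric("residueTable", function(x) standardGeneric("residueTable"))

#' C-alpha coordinates
#' @param x a \linkS4class{ProteinStructure}.
#' @param chain optional chain id filter.
#' @return numeric matrix (nResidues x 3); rownames are residue indices.
#'   Residues lacking a CA atom yield NA rows.
#' @export
setGeneric("caCoords", function(x, chain = NULL) standardGeneric("caCoords"))

#' Alignment row ids
#' @param x a \linkS4class{MsAlignment}.
#' @export
setGeneric("alignmentIds", function(x) standardGeneric("alignmentIds"))

#' Alignment rows (gapped strings)
#' @param x a \linkS4class{MsAlignment}.
#' @export
setGeneric("alignmentRows", function(x) standardGeneric("alignmentRows"))

#' Number of alignment columns
#' @param x a \linkS4class{MsAlignment}.
#' @export
setGeneric("alignmentNcol", function(x) standardGeneric("alignmentNcol"))

#' Column-to-residue index map
#'
#' For one alignment row, the 1-based residue index carried by each column
#' (NA at gap columns).  The map is strictly increasing over non-gap columns.
#'
#' @param x a \linkS4class{MsAlignment}.
#' @param id row id.
#' @return integer vector of length \code{alignmentNcol(x)}.
#' @export
setGeneric("columnMap", function(x, id) standardGeneric("columnMap"))

#' Ungapped sequence of an alignment row
#' @param x a \linkS4class{MsAlignment}.
#' @param id row id.
#' @return single character string without gaps.
#' @export
setGeneric("degappedRow", function(x, id) standardGeneric("degappedRow"))
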