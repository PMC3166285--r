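## Aligned-FASTA and sequence I/O through Biostrings.

#' Construct an alignment from gapped rows
#'
#' @param rows character vector of equal-length gapped strings ('-' gap).
#' @param ids character vector of unique ids.
#' @return a \linkS4class{MsAlignment}.
#' @export
msAlignment <- function(rows, ids) {
  new("MsAlignment", rowIds = unname(as.character(ids)),
      rows = unname(toupper(rows)))
}

#' Read an aligned FASTA file
#'
#' @param path aligned FASTA; all records must have equal length.
#' @return a \linkS4class{MsAlignment}.
#' @export
readAlignmentFasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("empty alignment file: ", path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids)) stop("duplicate ids in ", path)
  w <- Biostrings::width(ss)
  if (length(unique(w)) != 1L)
    stop("ragged rows in ", path, ": lengths ", paste(unique(w), collapse = ", "))
  msAlignment(as.character(ss), ids)
}

#' Write an alignment as aligned FASTA
#' @param x a \linkS4class{MsAlignment}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeAlignmentFasta <- function(x, path) {
  ss <- Biostrings::BStringSet(x@rows)
  names(ss) <- x@rowIds
  Biostrings::writeXStringSet(ss, path, width = 60L)
  invisible(path)
}

#' Read ungapped FASTA sequences
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
readSequencesFasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  out <- toupper(as.character(ss))
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' Write ungapped FASTA sequences
#' @param seqs named character vector.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeSequencesFasta <- function(seqs, path) {
  ss <- Biostrings::BStringSet(seqs)
  names(ss) <- names(seqs)
  Biostrings::writeXStringSet(ss, path, width = 60L)
  invisible(path)
}

#' @rdname alignmentIds
#' @export
setMethod("alignmentIds", "MsAlignment", function(x) x@rowIds)

#' @rdname alignmentRows
#' @export
setMethod("alignmentRows", "MsAlignment", function(x) {
  structure(x@rows, names = x@rowIds)
})

#' @rdname alignmentNcol
#' @export
setMethod("alignmentNcol", "MsAlignment", function(x) nchar(x@rows[1L]))

.alnRow <- function(x, id) {
  i <- match(id, x@rowIds)
  if (is.na(i)) stop("no alignment row with id '", id, "'")
  x@rows[i]
}

#' @rdname columnMap
#' @export
setMethod("columnMap", "MsAlignment", function(x, id) {
  ch <- strsplit(.alnRow(x, id), "")[[1L]]
  gap <- ch == "-"
  out <- cumsum(!gap)
  out[gap] <- NA_integer_
  as.integer(out)
})

#' @rdname degappedRow
#' @export
setMethod("degappedRow", "MsAlignment", function(x, id) {
  gsub("-", "", .alnRow(x, id), fixed = TRUE)
})

#' Alignment as a character matrix
#' @param x a \linkS4class{MsAlignment}.
#' @return character matrix (rows x columns), rownames = ids.
#' @export
alignmentMatrix <- function(x) {
  m <- do.call(rbind, strsplit(x@rows, ""))
  rownames(m) <- x@rowIds
  m
}
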