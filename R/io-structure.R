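## PDB coordinate I/O.  Parsing is delegated to bio3d::read.pdb; this layer
## applies the package's policies: one MODEL, altloc resolution by occupancy,
## water removal, residue bookkeeping.

.WATER <- c("HOH", "DOD", "WAT", "H2O")

#' Read a PDB-format structure
#'
#' Reads ATOM/HETATM records of one model.  Waters are dropped; for altloc
#' duplicates of the same atom the highest-occupancy conformer is kept, ties
#' broken in favour of altloc \code{'A'} (then alphabetically).  Insertion
#' codes are kept as part of residue identity.
#'
#' @param path PDB file.
#' @param modelIndex which MODEL block to read (1-based; default first).
#' @param id structure label; defaults to the file base name.
#' @param keepHetatm keep non-water HETATM records (default TRUE).
#' @return a \linkS4class{ProteinStructure}.
#' @export
readStructure <- function(path, modelIndex = 1L, id = NULL, keepHetatm = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  id <- id %||% sub("\\.(pdb|ent)$", "", basename(path), ignore.case = TRUE)
  src <- path
  lines <- readLines(path, warn = FALSE)
  nModels <- sum(grepl("^MODEL", lines))
  if (modelIndex > max(nModels, 1L))
    stop("requested model ", modelIndex, " but file has ", max(nModels, 1L))
  if (nModels > 0L && modelIndex > 1L) {
    starts <- grep("^MODEL", lines)
    ends <- grep("^ENDMDL", lines)
    if (length(ends) < length(starts)) ends <- c(ends, length(lines))
    src <- tempfile(fileext = ".pdb")
    on.exit(unlink(src), add = TRUE)
    writeLines(lines[starts[modelIndex]:ends[modelIndex]], src)
  }
  pdb <- suppressWarnings(bio3d::read.pdb(src, rm.alt = FALSE, verbose = FALSE))
  a <- pdb$atom
  a <- a[!(a$resid %in% .WATER), , drop = FALSE]
  if (!keepHetatm) a <- a[a$type == "ATOM", , drop = FALSE]
  if (!any(a$type == "ATOM")) stop("no ATOM records in ", path)
  a$insert[is.na(a$insert)] <- ""
  a$alt[is.na(a$alt)] <- ""
  a$chain[is.na(a$chain)] <- " "
  a$o[is.na(a$o)] <- 1
  ## altloc resolution: highest occupancy, then altloc '' < 'A' < 'B' ...
  key <- paste(a$chain, a$resno, a$insert, a$elety, sep = "\r")
  ord <- order(match(key, unique(key)), -a$o, a$alt)
  a <- a[ord, , drop = FALSE]
  a <- a[!duplicated(paste(a$chain, a$resno, a$insert, a$elety, sep = "\r")), ,
         drop = FALSE]
  ## restore file order of the surviving atoms
  a <- a[order(as.integer(rownames(a))), , drop = FALSE]
  el <- a$elesy
  miss <- is.na(el) | el == ""
  el[miss] <- elementFromAtomName(a$elety[miss])
  atoms <- data.frame(
    chain = a$chain, resno = a$resno, insert = a$insert, resid = a$resid,
    aa1 = aaThreeToOne(a$resid), elety = a$elety, element = toupper(el),
    x = a$x, y = a$y, z = a$z, occ = a$o, altloc = a$alt,
    stringsAsFactors = FALSE)
  atoms$isHeavy <- !(atoms$element %in% c("H", "D"))
  new("ProteinStructure", id = id, modelIndex = as.numeric(modelIndex),
      atoms = atoms)
}

#' Write a structure as a PDB file
#'
#' Coordinates are written in fixed-width PDB fields with 3 decimals, so a
#' read/write/read round trip reproduces coordinates exactly at that
#' precision.
#'
#' @param x a \linkS4class{ProteinStructure}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeStructure <- function(x, path) {
  a <- atomTable(x)
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
    resno = a$resno, resid = a$resid, chain = a$chain,
    insert = ifelse(a$insert == "", "", a$insert),
    elety = a$elety, o = a$occ, b = rep(0, nrow(a)),
    elesy = a$element)
  invisible(path)
}

#' @rdname atomTable
#' @export
setMethod("atomTable", "ProteinStructure", function(x) x@atoms)

#' @rdname residueTable
#' @export
setMethod("residueTable", "ProteinStructure", function(x) {
  a <- x@atoms
  key <- paste(a$chain, a$resno, a$insert, sep = "\r")
  first <- !duplicated(key)
  out <- data.frame(
    resIndex = seq_len(sum(first)),
    chain = a$chain[first], resno = a$resno[first], insert = a$insert[first],
    resid = a$resid[first], aa1 = a$aa1[first], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
})

## integer residue index (file order) for every atom row
atomResidueIndex <- function(x) {
  a <- x@atoms
  key <- paste(a$chain, a$resno, a$insert, sep = "\r")
  match(key, unique(key))
}

#' @rdname caCoords
#' @export
setMethod("caCoords", "ProteinStructure", function(x, chain = NULL) {
  a <- x@atoms
  idx <- atomResidueIndex(x)
  n <- max(idx)
  out <- matrix(NA_real_, nrow = n, ncol = 3,
                dimnames = list(seq_len(n), c("x", "y", "z")))
  ca <- which(a$elety == "CA" & a$element == "C")
  out[idx[ca], ] <- as.matrix(a[ca, c("x", "y", "z")])
  if (!is.null(chain)) {
    rt <- residueTable(x)
    out <- out[rt$chain %in% chain, , drop = FALSE]
  }
  out
})

#' One-letter sequence of a structure
#' @param x a \linkS4class{ProteinStructure}.
#' @param chain optional chain id filter.
#' @return single character string.
#' @export
structureSequence <- function(x, chain = NULL) {
  rt <- residueTable(x)
  if (!is.null(chain)) rt <- rt[rt$chain %in% chain, , drop = FALSE]
  paste(rt$aa1, collapse = "")
}
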