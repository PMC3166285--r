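## Least-squares rigid-body superposition and C-alpha RMSD machinery.

#' Kabsch superposition
#'
#' Least-squares rigid-body fit of \code{mov} onto \code{ref} (paired rows)
#' via singular value decomposition, with reflections excluded (the rotation
#' determinant is forced to +1).
#'
#' @param ref,mov numeric n x 3 matrices of paired coordinates, n >= 3 and
#'   not collinear.
#' @return a \linkS4class{Superposition}; \code{mov \%*\% t(rotation) +
#'   translation} superposes onto \code{ref}.
#' @export
kabschSuperpose <- function(ref, mov) {
  ref <- as.matrix(ref); mov <- as.matrix(mov)
  stopifnot(ncol(ref) == 3L, ncol(mov) == 3L)
  if (nrow(ref) != nrow(mov)) stop("ref and mov must pair row-for-row")
  if (nrow(ref) < 3L) stop("need at least 3 paired points")
  cr <- colMeans(ref); cm <- colMeans(mov)
  A <- sweep(ref, 2, cr); B <- sweep(mov, 2, cm)
  if (min(svd(A)$d[2], svd(B)$d[2]) < 1e-8 * max(1, max(abs(A)), max(abs(B))))
    stop("degenerate (collinear) coordinates: superposition is ill-defined")
  H <- crossprod(B, A)                 # 3x3 covariance, mov -> ref
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  fitted <- B %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - A)^2)))
  new("Superposition", rotation = R,
      translation = as.numeric(cr - R %*% cm), rmsd = rmsd)
}

#' Apply a superposition to coordinates
#' @param sup a \linkS4class{Superposition}.
#' @param coords numeric n x 3 matrix.
#' @return transformed n x 3 matrix.
#' @export
applySuperposition <- function(sup, coords) {
  sweep(as.matrix(coords) %*% t(sup@rotation), 2, -sup@translation)
}

## C-alpha coordinates of a structure at given alignment columns, or NULL
## with attr "missing" naming residues without a CA.
.caAtColumns <- function(struct, aln, columns) {
  map <- columnMap(aln, struct@id)
  ca <- caCoords(struct)
  idx <- map[columns]
  coords <- ca[idx, , drop = FALSE]
  coords
}

## columns ungapped in the given row ids
.sharedColumns <- function(aln, ids) {
  ok <- rep(TRUE, alignmentNcol(aln))
  for (id in ids) ok <- ok & !is.na(columnMap(aln, id))
  which(ok)
}

#' Pairwise C-alpha RMSD of two aligned structures
#'
#' Superposes the two structures on their mutually ungapped aligned C-alpha
#' pairs and returns the post-fit RMSD.  Symmetric in its arguments.
#'
#' @param structA,structB \linkS4class{ProteinStructure}s whose ids are
#'   alignment rows.
#' @param aln a \linkS4class{MsAlignment}.
#' @return RMSD in Angstrom.
#' @export
pairwiseCalphaRmsd <- function(structA, structB, aln) {
  cols <- .sharedColumns(aln, c(structA@id, structB@id))
  A <- .caAtColumns(structA, aln, cols)
  B <- .caAtColumns(structB, aln, cols)
  bad <- !stats::complete.cases(A) | !stats::complete.cases(B)
  if (any(bad)) {
    rtA <- residueTable(structA); rtB <- residueTable(structB)
    iA <- columnMap(aln, structA@id)[cols[bad]]
    iB <- columnMap(aln, structB@id)[cols[bad]]
    stop("missing C-alpha atoms at residues: ",
         paste(stats::na.omit(c(
           paste0(structA@id, ":", rtA$resno[iA]),
           paste0(structB@id, ":", rtB$resno[iB]))), collapse = ", "))
  }
  if (nrow(A) < 3L) stop("fewer than 3 mutually ungapped C-alpha pairs")
  kabschSuperpose(A, B)@rmsd
}

#' Per-column C-alpha RMSD profile of a superposed ensemble
#'
#' Superposes every structure onto the reference (over the columns ungapped
#' in the pair), then, for each column that is gap-free in all rows and has
#' a C-alpha in every structure, computes the RMSD of the equivalent
#' C-alpha positions from their centroid:
#' \code{sqrt(mean(||x_i - centroid||^2))}.  Columns with a gap, or with a
#' missing C-alpha in any structure (logged as a warning), are undefined.
#'
#' @param structures list of \linkS4class{ProteinStructure}s; ids must be
#'   alignment rows.
#' @param aln a \linkS4class{MsAlignment}.
#' @param referenceId id of the superposition frame (default: first
#'   structure).
#' @param superpose fit every structure onto the reference first (default);
#'   set FALSE when the ensemble is already in a common frame.
#' @return a \linkS4class{ColumnRmsdProfile}.
#' @export
columnRmsdProfile <- function(structures, aln,
                              referenceId = structures[[1L]]@id,
                              superpose = TRUE) {
  ids <- vapply(structures, function(s) s@id, "")
  if (!referenceId %in% ids) stop("reference '", referenceId, "' not in ensemble")
  ref <- structures[[match(referenceId, ids)]]
  ncols <- alignmentNcol(aln)
  n <- length(structures)
  ## superpose everything onto the reference frame
  placed <- vector("list", n)
  for (i in seq_len(n)) {
    s <- structures[[i]]
    if (!superpose || s@id == referenceId) {
      placed[[i]] <- caCoords(s)
      next
    }
    cols <- .sharedColumns(aln, c(referenceId, s@id))
    A <- .caAtColumns(ref, aln, cols)
    B <- .caAtColumns(s, aln, cols)
    keep <- stats::complete.cases(A) & stats::complete.cases(B)
    if (sum(keep) < 3L)
      stop("fewer than 3 shared C-alpha pairs for '", s@id, "'")
    sup <- kabschSuperpose(A[keep, , drop = FALSE], B[keep, , drop = FALSE])
    placed[[i]] <- applySuperposition(sup, caCoords(s))
  }
  hasGap <- logical(ncols)
  rmsd <- rep(NA_real_, ncols)
  maps <- lapply(structures, function(s) columnMap(aln, s@id))
  missingCa <- FALSE
  for (j in seq_len(ncols)) {
    idx <- vapply(maps, `[`, 0L, j)
    if (anyNA(idx)) { hasGap[j] <- TRUE; next }
    P <- t(vapply(seq_len(n), function(i) placed[[i]][idx[i], ], numeric(3)))
    if (anyNA(P)) { hasGap[j] <- TRUE; missingCa <- TRUE; next }
    if (n == 1L) { rmsd[j] <- 0; next }
    centroid <- colMeans(P)
    rmsd[j] <- sqrt(mean(rowSums(sweep(P, 2, centroid)^2)))
  }
  if (missingCa)
    warning("columns with missing C-alpha atoms were treated as gaps")
  new("ColumnRmsdProfile", rmsd = rmsd, hasGap = hasGap,
      nStructures = as.integer(n))
}
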