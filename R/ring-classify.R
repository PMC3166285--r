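## RING-type classification from zinc-ligand residue patterns.
##
## A RING domain coordinates two zinc ions through eight ordered metal-ligand
## positions; the residue identities at those positions name the type
## (C3HC4, C3H2C3, ...).  The scan finds admissible 8-position vectors under
## a spacing model; the rule table maps the 8 letters to a type label.

.LIGAND_ALPHABET <- c("C", "H", "D", "G", "S", "T")
.RING_REFERENCE <- c("C", "C", "C", "H", "C", "C", "C", "C")

#' Ligand spacing model
#'
#' Allowed residue-count gaps between consecutive metal-ligand positions and
#' the allowed letters at each of the 8 positions.  The default brackets
#' canonical RING spacing:
#' C-x(1,3)-C-x(8,40)-[CHDGST]-x(1,4)-[HC]-x(1,4)-[CHGD]-x(1,3)-C-x(3,50)-C-x(1,3)-[CD],
#' with Ser/Thr additionally admitted at positions 2 and 6 so that RING-S/T
#' patterns are scannable.
#'
#' @param gapRanges 7x2 integer matrix: min/max residues between consecutive
#'   ligand positions.
#' @param positionAlphabets list of 8 character vectors: allowed letters per
#'   position.
#' @return a \code{LigandSpacingModel} (list with class attribute).
#' @export
ligandSpacingModel <- function(gapRanges = NULL, positionAlphabets = NULL) {
  if (is.null(gapRanges))
    gapRanges <- rbind(c(1, 3), c(8, 40), c(1, 4), c(1, 4),
                       c(1, 3), c(3, 50), c(1, 3))
  gapRanges <- matrix(as.integer(gapRanges), ncol = 2)
  if (nrow(gapRanges) != 7L) stop("gapRanges must have 7 rows")
  if (any(gapRanges[, 1] > gapRanges[, 2])) stop("gap range with min > max")
  if (any(gapRanges[, 1] < 0)) stop("negative gap")
  if (is.null(positionAlphabets))
    positionAlphabets <- list(
      "C", c("C", "S", "T"), c("C", "H", "D", "G", "S", "T"), c("H", "C"),
      c("C", "H", "G", "D"), c("C", "S", "T"), "C", c("C", "D"))
  if (length(positionAlphabets) != 8L) stop("need 8 position alphabets")
  structure(list(gapRanges = gapRanges, positionAlphabets = positionAlphabets),
            class = "LigandSpacingModel")
}

#' Scan a sequence for admissible metal-ligand position vectors
#'
#' Depth-first search over positions satisfying the spacing model and the
#' per-position alphabets.  Overlapping candidates are allowed; vectors are
#' returned ordered by position vector (left-to-right, lexicographic).
#'
#' @param seq one sequence (character string) or a named length-1 vector.
#' @param model a \code{\link{ligandSpacingModel}}.
#' @return integer matrix, one row per candidate, 8 columns of 1-based
#'   positions; zero rows when no match.
#' @export
scanLigandPositions <- function(seq, model = ligandSpacingModel()) {
  s <- strsplit(toupper(seq[[1L]]), "")[[1L]]
  n <- length(s)
  hits <- list()
  allowed <- lapply(model$positionAlphabets, function(a) which(s %in% a))
  recurse <- function(pos, k) {
    if (k == 8L) { hits[[length(hits) + 1L]] <<- pos; return(invisible()) }
    lo <- pos[k] + model$gapRanges[k, 1] + 1L
    hi <- pos[k] + model$gapRanges[k, 2] + 1L
    cand <- allowed[[k + 1L]]
    for (p in cand[cand >= lo & cand <= hi])
      recurse(c(pos, p), k + 1L)
  }
  for (p1 in allowed[[1L]]) recurse(p1, 1L)
  if (length(hits) == 0L)
    return(matrix(integer(), ncol = 8,
                  dimnames = list(NULL, paste0("p", 1:8))))
  m <- do.call(rbind, hits)
  colnames(m) <- paste0("p", 1:8)
  m[do.call(order, as.data.frame(m)), , drop = FALSE]
}

#' Classify 8 ligand letters into a RING type
#'
#' Deterministic, total rule table keyed on the substitution set relative to
#' the C3HC4 reference pattern (C,C,C,H,C,C,C,C): no substitution is C3HC4;
#' His at position 5 is C3H2C3; Asp at position 8 is C3HC3D; the His moved
#' from position 4 to 5 is C4HC3; Gly at position 5 is C3HGC3; all-Cys is
#' C4C4; Asp at position 5 is RING-D; Ser/Thr at positions 2 and/or 6 is
#' RING-S/T; any letter outside the ligand alphabet, or any unnamed
#' combination, is unclassified.
#'
#' @param letters character vector of 8 letters, or an n x 8 character matrix
#'   for vectorised classification.
#' @return for a vector: list with \code{type} and \code{substitutions}
#'   (data.frame position/letter); for a matrix: character vector of labels.
#' @export
classifyRingType <- function(letters) {
  if (is.matrix(letters)) return(.classifyRingTypeMatrix(letters))
  stopifnot(length(letters) == 8L)
  lab <- .classifyRingTypeMatrix(matrix(toupper(letters), nrow = 1))
  diffs <- which(toupper(letters) != .RING_REFERENCE)
  list(type = lab,
       substitutions = data.frame(position = diffs,
                                  letter = toupper(letters)[diffs],
                                  stringsAsFactors = FALSE))
}

.classifyRingTypeMatrix <- function(m) {
  stopifnot(ncol(m) == 8L)
  m <- toupper(m)
  ok <- rowSums(matrix(m %in% .LIGAND_ALPHABET, nrow = nrow(m))) == 8L
  diff <- m != matrix(.RING_REFERENCE, nrow(m), 8, byrow = TRUE)
  nd <- rowSums(diff)
  lab <- rep("unclassified", nrow(m))
  lab[nd == 0L] <- "C3HC4"
  one <- nd == 1L
  lab[one & diff[, 5] & m[, 5] == "H"] <- "C3H2C3"
  lab[one & diff[, 5] & m[, 5] == "G"] <- "C3HGC3"
  lab[one & diff[, 5] & m[, 5] == "D"] <- "RING-D"
  lab[one & diff[, 8] & m[, 8] == "D"] <- "C3HC3D"
  lab[one & diff[, 4] & m[, 4] == "C"] <- "C4C4"
  lab[nd == 2L & diff[, 4] & diff[, 5] & m[, 4] == "C" & m[, 5] == "H"] <- "C4HC3"
  st <- nd >= 1L & rowSums(diff[, -c(2L, 6L), drop = FALSE]) == 0L &
    (!diff[, 2] | m[, 2] %in% c("S", "T")) &
    (!diff[, 6] | m[, 6] %in% c("S", "T"))
  lab[st] <- "RING-S/T"
  lab[!ok] <- "unclassified"
  lab
}

#' Classify one sequence
#'
#' Scans for ligand-position candidates and classifies the best one: fewest
#' substitutions from the C3HC4 reference, ties broken by the leftmost
#' (lexicographically smallest) position vector.  When no candidate exists
#' and \code{annotationHint = "U-box"}, the sequence is labelled U-box
#' (U-box domains keep the RING fold without the metal-chelating residues);
#' otherwise it is unclassified.
#'
#' @param seq one sequence string.
#' @param model a \code{\link{ligandSpacingModel}}.
#' @param annotationHint \code{"none"} or \code{"U-box"}.
#' @param seqId label for the output.
#' @return list (class \code{RingAssignment}) with \code{seq_id},
#'   \code{type}, \code{ligand_positions}, \code{ligand_letters},
#'   \code{substitutions}.
#' @export
classifySequence <- function(seq, model = ligandSpacingModel(),
                             annotationHint = c("none", "U-box"),
                             seqId = names(seq) %||% "seq") {
  annotationHint <- match.arg(annotationHint)
  cand <- scanLigandPositions(seq, model)
  if (nrow(cand) == 0L) {
    type <- if (annotationHint == "U-box") "U-box" else "unclassified"
    return(structure(list(seq_id = seqId, type = type,
                          ligand_positions = integer(0),
                          ligand_letters = character(0),
                          substitutions = data.frame(position = integer(),
                                                     letter = character())),
                     class = "RingAssignment"))
  }
  s <- strsplit(toupper(seq[[1L]]), "")[[1L]]
  letters <- matrix(s[cand], ncol = 8)
  nsub <- rowSums(letters != matrix(.RING_REFERENCE, nrow(letters), 8,
                                    byrow = TRUE))
  ## candidates are already in lexicographic position order, so the first
  ## minimal-substitution row is the leftmost one
  best <- which(nsub == min(nsub))[1L]
  cls <- classifyRingType(letters[best, ])
  structure(list(seq_id = seqId, type = cls$type,
                 ligand_positions = unname(cand[best, ]),
                 ligand_letters = letters[best, ],
                 substitutions = cls$substitutions),
            class = "RingAssignment")
}

#' @export
print.RingAssignment <- function(x, ...) {
  cat(sprintf("RingAssignment '%s': %s\n", x$seq_id, x$type))
  if (length(x$ligand_positions))
    cat("  ligands:", paste(x$ligand_letters, x$ligand_positions,
                            sep = "", collapse = " "), "\n")
  invisible(x)
}

#' Classify a set of sequences
#'
#' @param seqs named character vector of sequences.
#' @param model a \code{\link{ligandSpacingModel}}.
#' @param hints optional named character vector of annotation hints
#'   (\code{"U-box"}) keyed by sequence id.
#' @return data.frame: seq_id, type, positions (comma-joined), letters,
#'   n_substitutions.
#' @export
classifySequences <- function(seqs, model = ligandSpacingModel(), hints = NULL) {
  ids <- names(seqs) %||% paste0("seq", seq_along(seqs))
  rows <- lapply(seq_along(seqs), function(i) {
    hint <- if (!is.null(hints) && ids[i] %in% names(hints) &&
                hints[[ids[i]]] == "U-box") "U-box" else "none"
    a <- classifySequence(seqs[[i]], model, annotationHint = hint,
                          seqId = ids[i])
    data.frame(seq_id = a$seq_id, type = a$type,
               positions = paste(a$ligand_positions, collapse = ","),
               letters = paste(a$ligand_letters, collapse = ""),
               n_substitutions = nrow(a$substitutions),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Scan for the 12-ligand three-zinc pattern (C6H3C2D)
#'
#' The solved three-zinc RING domains carry 12 metal-ligand positions; the
#' ligand order of the third site is not well established, so this scan is a
#' composition test (flagged putative): 12 admissible positions whose letters
#' contain exactly 3 His, at most one Asp restricted to positions 8 or 12,
#' and Cys elsewhere.  Disabled by default in \code{classifySequences}.
#'
#' @param seq one sequence string.
#' @param gapRange allowed residue gap between consecutive positions.
#' @return integer matrix of candidate 12-position vectors (possibly empty),
#'   with attribute \code{putative = TRUE}.
#' @export
scanTripleZinc <- function(seq, gapRange = c(1L, 45L)) {
  s <- strsplit(toupper(seq[[1L]]), "")[[1L]]
  sites <- which(s %in% c("C", "H", "D"))
  hits <- list()
  recurse <- function(pos) {
    k <- length(pos)
    if (k == 12L) {
      lets <- s[pos]
      dpos <- which(lets == "D")
      if (sum(lets == "H") == 3L && length(dpos) <= 1L &&
          all(dpos %in% c(8L, 12L)) &&
          sum(lets == "C") == 12L - 3L - length(dpos))
        hits[[length(hits) + 1L]] <<- pos
      return(invisible())
    }
    lo <- pos[k] + gapRange[1] + 1L
    hi <- pos[k] + gapRange[2] + 1L
    for (p in sites[sites >= lo & sites <= hi]) recurse(c(pos, p))
  }
  for (p1 in sites[s[sites] == "C"]) recurse(p1)
  m <- if (length(hits)) do.call(rbind, hits) else matrix(integer(), ncol = 12)
  attr(m, "putative") <- TRUE
  m
}
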