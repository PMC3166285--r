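## Column consensus and conservation scoring with a residue-class alphabet.

#' Residue-class alphabet for consensus calling
#'
#' The class inventory and symbols used in consensus rows of RING-domain
#' alignments: aliphatic (I,V,L) 'l'; aromatic (Y,H,W,F) '@'; hydrophobic
#' (W,F,Y,M,L,I,V,A,C,T,H) 'h'; alcohol (S,T) 'o'; polar (D,E,H,K,N,Q,R,S,T)
#' 'p'; tiny (A,G,C,S) 't'; small (A,G,C,S,V,N,D,T,P) 's'; bulky
#' (E,F,I,K,L,M,Q,R,W,Y) 'b'; positive (K,R,H) '+'; negative (D,E) '-';
#' charged (D,E,K,R,H) 'c'.
#'
#' The returned list is ordered by calling preference: single-letter identity
#' is checked first (by \code{\link{columnProfile}}), then the six specific
#' classes from smallest membership up, then charged, hydrophobic, small,
#' polar, bulky.  The first class whose aggregate fraction reaches the level
#' threshold wins.
#'
#' @return named list of character vectors (names are the class symbols),
#'   in tie-break order.
#' @export
residueClassAlphabet <- function() {
  list(
    "o" = c("S", "T"),
    "-" = c("D", "E"),
    "l" = c("I", "V", "L"),
    "+" = c("K", "R", "H"),
    "@" = c("Y", "H", "W", "F"),
    "t" = c("A", "G", "C", "S"),
    "c" = c("D", "E", "K", "R", "H"),
    "h" = c("W", "F", "Y", "M", "L", "I", "V", "A", "C", "T", "H"),
    "s" = c("A", "G", "C", "S", "V", "N", "D", "T", "P"),
    "p" = c("D", "E", "H", "K", "N", "Q", "R", "S", "T"),
    "b" = c("E", "F", "I", "K", "L", "M", "Q", "R", "W", "Y"))
}

## letter counts of one column over the 20 standard residues; gaps and
## non-standard letters (X) excluded from class scoring, gaps excluded from
## the denominator.
.columnCounts <- function(aln, column) {
  ch <- substring(aln@rows, column, column)
  ch <- ch[ch != "-"]
  nNongap <- length(ch)
  counts <- table(factor(ch[ch %in% .STANDARD_AA], levels = .STANDARD_AA))
  list(nNongap = nNongap, counts = as.numeric(counts),
       letters = .STANDARD_AA)
}

#' Profile one alignment column
#'
#' Computes per-letter fractions (denominator: non-gap entries), the
#' consensus symbol and level, and the conservation index.  The consensus is
#' a single letter when one letter's fraction reaches the threshold;
#' otherwise the preferred residue class (see
#' \code{\link{residueClassAlphabet}}) whose aggregate fraction reaches it;
#' otherwise none.  Columns with more than 50\% gaps are flagged low-support.
#'
#' @param aln a \linkS4class{MsAlignment}.
#' @param column 1-based column index.
#' @param alphabet class alphabet (tie-break order honoured).
#' @param levelThreshold consensus level threshold (default 0.8).
#' @return list: column, n_nongap, fractions (named, 20 letters),
#'   class_fractions (named by symbol), consensus_symbol (or NA),
#'   consensus_level, conservation_index, low_support.
#' @export
columnProfile <- function(aln, column, alphabet = residueClassAlphabet(),
                          levelThreshold = 0.8) {
  stopifnot(column >= 1L, column <= alignmentNcol(aln))
  cc <- .columnCounts(aln, column)
  nrow <- length(aln@rows)
  frac <- if (cc$nNongap > 0) cc$counts / cc$nNongap else rep(0, 20)
  names(frac) <- cc$letters
  classFrac <- vapply(alphabet, function(memb) sum(frac[memb]), numeric(1))
  symbol <- NA_character_
  level <- 0
  if (cc$nNongap > 0) {
    if (max(frac) >= levelThreshold) {
      symbol <- cc$letters[which.max(frac)]
      level <- max(frac)
    } else {
      hit <- which(classFrac >= levelThreshold)
      if (length(hit)) {
        symbol <- names(alphabet)[hit[1L]]
        level <- classFrac[hit[1L]]
      }
    }
  }
  list(column = column, n_nongap = cc$nNongap, fractions = frac,
       class_fractions = classFrac, consensus_symbol = symbol,
       consensus_level = unname(level),
       conservation_index = conservationIndex(frac, cc$nNongap),
       low_support = cc$nNongap < nrow / 2)
}

#' Conservation index of a column (0-9)
#'
#' Entropy-based score: \code{round(9 * (1 - H / log(20)))} where H is the
#' Shannon entropy (natural log) of the non-gap letter frequencies over the
#' 20 standard residues.  A single-letter column scores 9, a uniform column
#' 0, an all-gap column 0.  Rounding is floor(x + 0.5), so .5 always rounds
#' up.
#'
#' @param fractions named numeric vector of letter fractions (sums to 1 over
#'   the standard letters present).
#' @param nNongap number of non-gap entries (0 forces index 0).
#' @return integer in 0..9.
#' @export
conservationIndex <- function(fractions, nNongap = sum(fractions) > 0) {
  if (!nNongap || sum(fractions) <= 0) return(0L)
  p <- fractions[fractions > 0]
  p <- p / sum(p)
  H <- -sum(p * log(p))
  idx <- floor(9 * (1 - H / log(20)) + 0.5)
  as.integer(min(max(idx, 0), 9))
}

#' Profile every column of an alignment
#'
#' @inheritParams columnProfile
#' @return data.frame: column, n_nongap, consensus_symbol, consensus_level,
#'   conservation_index, low_support.
#' @export
profileAlignment <- function(aln, alphabet = residueClassAlphabet(),
                             levelThreshold = 0.8) {
  rows <- lapply(seq_len(alignmentNcol(aln)), function(j) {
    p <- columnProfile(aln, j, alphabet, levelThreshold)
    data.frame(column = j, n_nongap = p$n_nongap,
               consensus_symbol = p$consensus_symbol %||% NA_character_,
               consensus_level = p$consensus_level,
               conservation_index = p$conservation_index,
               low_support = p$low_support, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Call conserved columns
#'
#' Columns with a consensus symbol and conservation index strictly above the
#' index threshold, optionally restricted to SCR columns.  Columns whose
#' consensus is an invariant Cys or His (the zinc-chelating ligands) are
#' reported separately (\code{is_ligand}) and excluded from the additional
#' conserved-residue list.
#'
#' @param aln a \linkS4class{MsAlignment}.
#' @param scrSegments optional SCR data.frame (\code{start_col},
#'   \code{end_col}); when given, only columns inside a segment are called.
#' @param levelThreshold consensus level threshold (default 0.8).
#' @param indexThreshold conservation-index threshold; called columns must
#'   exceed it (default 4).
#' @param alphabet class alphabet.
#' @return list: \code{profile} (full per-column data.frame with
#'   \code{called} and \code{is_ligand} flags), \code{called_columns}
#'   (non-ligand conserved columns), \code{ligand_columns}.
#' @export
callConservedColumns <- function(aln, scrSegments = NULL,
                                 levelThreshold = 0.8, indexThreshold = 4,
                                 alphabet = residueClassAlphabet()) {
  prof <- profileAlignment(aln, alphabet, levelThreshold)
  inScr <- rep(TRUE, nrow(prof))
  if (!is.null(scrSegments) && nrow(scrSegments) > 0) {
    inScr <- rep(FALSE, nrow(prof))
    for (i in seq_len(nrow(scrSegments)))
      inScr[scrSegments$start_col[i]:scrSegments$end_col[i]] <- TRUE
  }
  conserved <- !is.na(prof$consensus_symbol) &
    prof$conservation_index > indexThreshold & inScr
  prof$is_ligand <- conserved & prof$consensus_symbol %in% c("C", "H")
  prof$called <- conserved & !prof$is_ligand
  list(profile = prof,
       called_columns = prof$column[prof$called],
       ligand_columns = prof$column[prof$is_ligand])
}

## does a profiled column qualify for a hydrophobic role?  Either the
## hydrophobic-class aggregate reaches the threshold, or the identity
## consensus is Pro (the C-loop hydrophobic role is mainly Pro, which the
## printed hydrophobic class does not contain).
.isHydroColumn <- function(p, levelThreshold) {
  p$class_fractions[["h"]] >= levelThreshold ||
    identical(p$consensus_symbol, "P")
}

.isPolarColumn <- function(p, levelThreshold) {
  p$class_fractions[["p"]] >= levelThreshold ||
    p$class_fractions[["c"]] >= levelThreshold
}

#' Assign equivalent-residue roles to conserved columns
#'
#' Maps conserved non-ligand columns to the six equivalent-residue roles by
#' SCR region: the N-loop hydrophobic column is hydro1; the beta-alpha
#' region's hydrophobic columns, in order, hydro2 and hydro3; the C-loop's
#' hydro4; the beta-alpha polar column polar1 (alpha-helix) and the C-loop
#' polar column polar2.  Surplus or missing columns are reported in
#' \code{diagnostics}, never silently dropped.
#'
#' @param aln a \linkS4class{MsAlignment}.
#' @param calledColumns integer vector of conserved non-ligand columns.
#' @param scrSegments data.frame with \code{start_col}, \code{end_col},
#'   \code{region_label} in \code{c("N-loop","beta","beta-alpha","C-loop")}.
#' @param alphabet class alphabet.
#' @param levelThreshold consensus level threshold.
#' @return list: \code{roles} data.frame (role, column, consensus_symbol),
#'   \code{per_sequence} data.frame of residue indices (one row per
#'   alignment row, one column per assigned role), \code{diagnostics}
#'   character vector.
#' @export
assignEquivalentResidues <- function(aln, calledColumns, scrSegments,
                                     alphabet = residueClassAlphabet(),
                                     levelThreshold = 0.8) {
  stopifnot("region_label" %in% names(scrSegments))
  regionOf <- function(col) {
    i <- which(scrSegments$start_col <= col & scrSegments$end_col >= col)
    if (length(i)) scrSegments$region_label[i[1L]] else NA_character_
  }
  diags <- character(0)
  cols <- sort(unique(as.integer(calledColumns)))
  info <- lapply(cols, function(j) {
    p <- columnProfile(aln, j, alphabet, levelThreshold)
    list(column = j, region = regionOf(j), profile = p,
         hydro = .isHydroColumn(p, levelThreshold),
         polar = .isPolarColumn(p, levelThreshold))
  })
  pick <- function(region, want, nWant, roleNames) {
    sel <- Filter(function(z) identical(z$region, region) && z[[want]], info)
    if (length(sel) < nWant)
      diags <<- c(diags, sprintf("region %s: expected %d %s column(s), found %d",
                                 region, nWant, want, length(sel)))
    if (length(sel) > nWant)
      diags <<- c(diags, sprintf(
        "region %s: %d surplus %s column(s) at %s", region,
        length(sel) - nWant, want,
        paste(vapply(sel[-seq_len(nWant)], `[[`, 0L, "column"), collapse = ",")))
    sel <- utils::head(sel, nWant)
    if (length(sel) == 0L) return(NULL)
    data.frame(role = roleNames[seq_along(sel)],
               column = vapply(sel, `[[`, 0L, "column"),
               consensus_symbol = vapply(sel, function(z)
                 z$profile$consensus_symbol %||% NA_character_, ""),
               stringsAsFactors = FALSE)
  }
  roles <- rbind(
    pick("N-loop", "hydro", 1L, "hydro1"),
    pick("beta-alpha", "hydro", 2L, c("hydro2", "hydro3")),
    pick("C-loop", "hydro", 1L, "hydro4"),
    pick("beta-alpha", "polar", 1L, "polar1"),
    pick("C-loop", "polar", 1L, "polar2"))
  unassigned <- Filter(function(z)
    is.na(z$region) || !(z$column %in% roles$column), info)
  if (length(unassigned))
    diags <- c(diags, sprintf("unassigned conserved column(s): %s",
                              paste(vapply(unassigned, `[[`, 0L, "column"),
                                    collapse = ",")))
  perSeq <- NULL
  if (!is.null(roles) && nrow(roles) > 0) {
    perSeq <- data.frame(seq_id = alignmentIds(aln), stringsAsFactors = FALSE)
    for (k in seq_len(nrow(roles))) {
      maps <- vapply(alignmentIds(aln), function(id)
        columnMap(aln, id)[roles$column[k]], integer(1))
      perSeq[[roles$role[k]]] <- unname(maps)
    }
  }
  list(roles = roles, per_sequence = perSeq, diagnostics = diags)
}
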