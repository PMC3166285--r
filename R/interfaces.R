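## E2/E3 intermolecular interface analysis: tiered residue contacts,
## backbone hydrogen bonds, SCR region assignment.

#' Contact extraction parameters
#'
#' @param contactCutoff residue contact cutoff, Angstrom (default 4.0).
#' @param closeCutoff close-approach cutoff, Angstrom (default 3.5; must
#'   not exceed \code{contactCutoff}).
#' @return list with class \code{ContactParams}.
#' @export
contactParams <- function(contactCutoff = 4.0, closeCutoff = 3.5) {
  stopifnot(closeCutoff <= contactCutoff, closeCutoff > 0)
  structure(list(contactCutoff = contactCutoff, closeCutoff = closeCutoff),
            class = "ContactParams")
}

#' Residue selection specification
#'
#' @param chain chain id.
#' @param start,end optional inclusive author residue-number range.
#' @return list with class \code{ResidueSelection}.
#' @export
residueSelection <- function(chain, start = NULL, end = NULL) {
  structure(list(chain = chain, start = start, end = end),
            class = "ResidueSelection")
}

#' Parse a CHAIN[:START-END] selection string
#' @param spec e.g. \code{"A"} or \code{"A:381-420"}.
#' @return a \code{\link{residueSelection}}.
#' @export
parseSelection <- function(spec) {
  m <- regmatches(spec, regexec("^([^:]+)(:(-?[0-9]+)-(-?[0-9]+))?$", spec))[[1]]
  if (length(m) == 0L) stop("bad selection spec: ", spec)
  if (m[3] == "") residueSelection(m[2])
  else residueSelection(m[2], as.integer(m[4]), as.integer(m[5]))
}

## residue indices matched by a selection
.resolveSelection <- function(structure, sel) {
  rt <- residueTable(structure)
  keep <- rt$chain == sel$chain
  if (!is.null(sel$start)) keep <- keep & rt$resno >= sel$start
  if (!is.null(sel$end)) keep <- keep & rt$resno <= sel$end
  rt$resIndex[keep]
}

#' Extract tiered inter-chain residue contacts
#'
#' For every residue pair across the two (disjoint) selections whose minimum
#' heavy-atom distance is at or below the contact cutoff, one record; the
#' tier is \code{"close"} at or below the close cutoff, else
#' \code{"contact"} (boundaries inclusive).  Sorted by E3 residue then
#' distance.
#'
#' @param structure a \linkS4class{ProteinStructure} holding both chains.
#' @param e3Selection,e2Selection \code{\link{residueSelection}}s (or
#'   CHAIN[:START-END] strings).
#' @param params a \code{\link{contactParams}}.
#' @return data.frame: e3_resIndex, e3_chain, e3_resno, e3_aa1,
#'   e2_resIndex, e2_chain, e2_resno, e2_aa1, min_distance, tier.
#' @export
extractContacts <- function(structure, e3Selection, e2Selection,
                            params = contactParams()) {
  if (is.character(e3Selection)) e3Selection <- parseSelection(e3Selection)
  if (is.character(e2Selection)) e2Selection <- parseSelection(e2Selection)
  e3 <- .resolveSelection(structure, e3Selection)
  e2 <- .resolveSelection(structure, e2Selection)
  if (length(e3) == 0L) stop("empty E3 selection")
  if (length(e2) == 0L) stop("empty E2 selection")
  if (length(intersect(e3, e2))) stop("E3 and E2 selections overlap")
  d <- .minResidueDistances(structure, e3, e2)
  rt <- residueTable(structure)
  hit <- which(d <= params$contactCutoff, arr.ind = TRUE)
  if (nrow(hit) == 0L)
    return(data.frame(e3_resIndex = integer(), e3_chain = character(),
                      e3_resno = integer(), e3_aa1 = character(),
                      e2_resIndex = integer(), e2_chain = character(),
                      e2_resno = integer(), e2_aa1 = character(),
                      min_distance = numeric(), tier = character(),
                      stringsAsFactors = FALSE))
  iE3 <- e3[hit[, 1]]; iE2 <- e2[hit[, 2]]
  dist <- d[hit]
  out <- data.frame(
    e3_resIndex = iE3,
    e3_chain = rt$chain[iE3], e3_resno = rt$resno[iE3], e3_aa1 = rt$aa1[iE3],
    e2_resIndex = iE2,
    e2_chain = rt$chain[iE2], e2_resno = rt$resno[iE2], e2_aa1 = rt$aa1[iE2],
    min_distance = dist,
    tier = ifelse(dist <= params$closeCutoff, "close", "contact"),
    stringsAsFactors = FALSE)
  out <- out[order(out$e3_resIndex, out$min_distance, out$e2_resIndex), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Number of distinct E3 residues in close approach
#'
#' Distinct E3 residues with at least one close-tier contact record — the
#' per-complex count compared across E2/E3 cocrystals.
#'
#' @param records data.frame from \code{\link{extractContacts}}.
#' @return integer count.
#' @export
countCloseE3Residues <- function(records) {
  length(unique(records$e3_resIndex[records$tier == "close"]))
}

#' Detect backbone hydrogen bonds across the interface
#'
#' Cross-selection backbone amide-nitrogen / carbonyl-oxygen pairs within
#' the distance cutoff, in both donor/acceptor directions.  Crystal
#' structures usually lack hydrogens, so the backbone N stands in for the
#' amide proton and no angle criterion is applied.
#'
#' @param structure a \linkS4class{ProteinStructure}.
#' @param e3Selection,e2Selection selections (objects or strings).
#' @param cutoff N...O distance cutoff, Angstrom (default 3.5).
#' @return data.frame: donor_chain, donor_resno, acceptor_chain,
#'   acceptor_resno, distance.
#' @export
detectBackboneHbonds <- function(structure, e3Selection, e2Selection,
                                 cutoff = 3.5) {
  if (is.character(e3Selection)) e3Selection <- parseSelection(e3Selection)
  if (is.character(e2Selection)) e2Selection <- parseSelection(e2Selection)
  a <- atomTable(structure)
  ridx <- atomResidueIndex(structure)
  selA <- .resolveSelection(structure, e3Selection)
  selB <- .resolveSelection(structure, e2Selection)
  pairsFor <- function(nSel, oSel) {
    ni <- which(a$elety == "N" & ridx %in% nSel)
    oi <- which(a$elety == "O" & ridx %in% oSel)
    if (!length(ni) || !length(oi)) return(NULL)
    XN <- as.matrix(a[ni, c("x", "y", "z")])
    XO <- as.matrix(a[oi, c("x", "y", "z")])
    d2 <- outer(rowSums(XN^2), rowSums(XO^2), `+`) - 2 * XN %*% t(XO)
    hit <- which(sqrt(pmax(d2, 0)) <= cutoff, arr.ind = TRUE)
    if (nrow(hit) == 0L) return(NULL)
    data.frame(
      donor_chain = a$chain[ni[hit[, 1]]],
      donor_resno = a$resno[ni[hit[, 1]]],
      acceptor_chain = a$chain[oi[hit[, 2]]],
      acceptor_resno = a$resno[oi[hit[, 2]]],
      distance = sqrt(pmax(d2, 0))[hit], stringsAsFactors = FALSE)
  }
  out <- rbind(pairsFor(selA, selB), pairsFor(selB, selA))
  if (is.null(out))
    out <- data.frame(donor_chain = character(), donor_resno = integer(),
                      acceptor_chain = character(), acceptor_resno = integer(),
                      distance = numeric(), stringsAsFactors = FALSE)
  out[order(out$donor_chain, out$donor_resno), , drop = FALSE]
}

#' Assign contact residues to SCR regions
#'
#' Maps each E3 contact residue to its alignment column and labels it I
#' (N-loop), II (alpha-helix of the beta-alpha region) or III (C-loop) when
#' the column falls inside the corresponding labelled SCR, else none.
#'
#' @param records data.frame from \code{\link{extractContacts}}.
#' @param scrSegments labelled SCR data.frame (\code{region_label} in
#'   N-loop/beta/beta-alpha/C-loop).
#' @param aln a \linkS4class{MsAlignment} containing the E3 row.
#' @param e3Id alignment row id of the E3 structure.
#' @param hbonds optional data.frame from
#'   \code{\link{detectBackboneHbonds}}.
#' @return list (\code{InterfaceSummary}): \code{residues} data.frame
#'   (e3 residue, column, region in I/II/III/none),
#'   \code{n_contact_residues_e3}, \code{n_close_residues_e3},
#'   \code{hbonds}, \code{diagnostics}.
#' @export
assignContactsToRegions <- function(records, scrSegments, aln, e3Id,
                                    hbonds = NULL) {
  regionCode <- c("N-loop" = "I", "beta-alpha" = "II", "C-loop" = "III")
  map <- columnMap(aln, e3Id)
  diags <- character(0)
  resIdx <- sort(unique(records$e3_resIndex))
  rows <- lapply(resIdx, function(ri) {
    col <- which(map == ri)[1L]
    region <- "none"
    if (is.na(col)) {
      diags <<- c(diags, sprintf("E3 residue %d not mappable to an alignment column", ri))
      col <- NA_integer_
    } else {
      seg <- which(scrSegments$start_col <= col & scrSegments$end_col >= col)
      if (length(seg)) {
        lab <- scrSegments$region_label[seg[1L]]
        if (!is.na(lab) && lab %in% names(regionCode))
          region <- regionCode[[lab]]
      }
    }
    sub <- records[records$e3_resIndex == ri, ]
    data.frame(e3_resIndex = ri, e3_chain = sub$e3_chain[1L],
               e3_resno = sub$e3_resno[1L], e3_aa1 = sub$e3_aa1[1L],
               column = col, region = region,
               close = any(sub$tier == "close"), stringsAsFactors = FALSE)
  })
  residues <- if (length(rows)) do.call(rbind, rows) else
    data.frame(e3_resIndex = integer(), e3_chain = character(),
               e3_resno = integer(), e3_aa1 = character(),
               column = integer(), region = character(), close = logical(),
               stringsAsFactors = FALSE)
  list(residues = residues,
       n_contact_residues_e3 = nrow(residues),
       n_close_residues_e3 = sum(residues$close),
       hbonds = hbonds, diagnostics = diags)
}
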