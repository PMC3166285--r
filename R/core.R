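## Hydrophobic patch and spatial-proximity analysis.

## minimum heavy-atom distance between every residue pair of two atom
## subsets; returns a matrix indexed by residue index
.minResidueDistances <- function(structure, idxA, idxB) {
  a <- atomTable(structure)
  ridx <- atomResidueIndex(structure)
  heavy <- a$isHeavy
  selA <- which(heavy & ridx %in% idxA)
  selB <- which(heavy & ridx %in% idxB)
  XA <- as.matrix(a[selA, c("x", "y", "z")])
  XB <- as.matrix(a[selB, c("x", "y", "z")])
  ## all-pair atom distances, then per residue-pair minimum
  d2 <- outer(rowSums(XA^2), rowSums(XB^2), `+`) - 2 * XA %*% t(XB)
  d2[d2 < 0] <- 0
  d <- sqrt(d2)
  rA <- ridx[selA]; rB <- ridx[selB]
  out <- matrix(Inf, length(idxA), length(idxB),
                dimnames = list(idxA, idxB))
  for (i in seq_along(idxA)) {
    rows <- rA == idxA[i]
    if (!any(rows)) next
    for (j in seq_along(idxB)) {
      cols <- rB == idxB[j]
      if (any(cols)) out[i, j] <- min(d[rows, cols])
    }
  }
  out
}

.HYDROPHOBIC_SET <- c("W", "F", "Y", "M", "L", "I", "V", "A", "C", "T", "H")

#' Hydrophobic residues within a distance cutoff of a query residue
#'
#' Returns hydrophobic-class residues whose minimum heavy-atom distance to
#' the query residue is at or below the cutoff.  The query itself and its
#' sequence neighbours at offset +-1 in the same chain are excluded, so
#' trivially bonded contacts do not count.
#'
#' @param structure a \linkS4class{ProteinStructure}.
#' @param resIndex global residue index of the query (see
#'   \code{\link{residueTable}}).
#' @param cutoff heavy-atom distance cutoff in Angstrom (default 4.0).
#' @return data.frame of neighbour residues with \code{min_distance}.
#' @export
hydrophobicNeighbors <- function(structure, resIndex, cutoff = 4.0) {
  rt <- residueTable(structure)
  if (!resIndex %in% rt$resIndex) stop("no residue with index ", resIndex)
  q <- rt[rt$resIndex == resIndex, ]
  cand <- rt[rt$aa1 %in% .HYDROPHOBIC_SET &
               rt$resIndex != resIndex &
               !(rt$chain == q$chain & abs(rt$resno - q$resno) == 1L), ,
             drop = FALSE]
  if (nrow(cand) == 0L)
    return(cbind(rt[0, ], min_distance = numeric(0)))
  d <- .minResidueDistances(structure, resIndex, cand$resIndex)
  keep <- d[1, ] <= cutoff
  out <- cbind(cand[keep, , drop = FALSE], min_distance = unname(d[1, keep]))
  rownames(out) <- NULL
  out[order(out$min_distance), , drop = FALSE]
}

#' Validate the hydrophobic patch around the central residue
#'
#' The four equivalent hydrophobic residues cluster around the second
#' (central) one: the patch is valid when the minimum heavy-atom distance
#' from each of hydro1, hydro3 and hydro4 to hydro2 is below the cutoff.
#'
#' @param structure a \linkS4class{ProteinStructure}.
#' @param hydroIndices named integer vector with elements \code{hydro1},
#'   \code{hydro2}, \code{hydro3}, \code{hydro4} (global residue indices).
#' @param cutoff distance cutoff in Angstrom (default 4.0).
#' @return list: \code{valid} (TRUE/FALSE, NA when indeterminate),
#'   \code{distances} data.frame (residue role, min distance to hydro2),
#'   \code{diagnostics}.
#' @export
validatePatch <- function(structure, hydroIndices, cutoff = 4.0) {
  need <- c("hydro1", "hydro2", "hydro3", "hydro4")
  if (!all(need %in% names(hydroIndices)))
    stop("hydroIndices must name hydro1..hydro4")
  rt <- residueTable(structure)
  missing <- need[!hydroIndices[need] %in% rt$resIndex |
                    is.na(hydroIndices[need])]
  if (length(missing))
    return(list(valid = NA,
                distances = NULL,
                diagnostics = paste("unresolvable residue(s):",
                                    paste(missing, collapse = ", "))))
  others <- c("hydro1", "hydro3", "hydro4")
  d <- .minResidueDistances(structure, hydroIndices[others],
                            hydroIndices[["hydro2"]])
  dist <- data.frame(role = others,
                     resIndex = unname(hydroIndices[others]),
                     min_distance_to_central = unname(d[, 1]),
                     stringsAsFactors = FALSE)
  list(valid = all(dist$min_distance_to_central < cutoff),
       distances = dist, diagnostics = character(0))
}

#' Hydrophobic patch around the central residue
#'
#' Collects the hydrophobic residues reachable from the central (hydro2)
#' residue within the cutoff, i.e. the query's hydrophobic neighbours plus
#' the query.
#'
#' @inheritParams hydrophobicNeighbors
#' @param centralIndex global residue index of the central hydrophobic
#'   residue.
#' @return list: \code{central} residue row, \code{members} data.frame of
#'   patch members with distances to the central residue.
#' @export
hydrophobicPatch <- function(structure, centralIndex, cutoff = 4.0) {
  rt <- residueTable(structure)
  nb <- hydrophobicNeighbors(structure, centralIndex, cutoff)
  list(central = rt[rt$resIndex == centralIndex, ], members = nb)
}
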