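## Solvent-accessible surface area by sphere-point sampling (Shrake-Rupley).

#' Core/surface analysis parameters
#'
#' @param neighborCutoff heavy-atom distance cutoff for hydrophobic
#'   neighbour search, Angstrom (default 4.0).
#' @param burialRelSasa relative-SASA ceiling below which a residue counts
#'   as buried (default 0.10).
#' @param probeRadius solvent probe radius, Angstrom (default 1.4).
#' @param spherePoints number of sample points per atom (default 960).
#' @return list with class \code{CoreParams}.
#' @export
coreParams <- function(neighborCutoff = 4.0, burialRelSasa = 0.10,
                       probeRadius = 1.4, spherePoints = 960L) {
  stopifnot(neighborCutoff > 0, burialRelSasa > 0, probeRadius > 0,
            spherePoints > 0)
  structure(list(neighborCutoff = neighborCutoff,
                 burialRelSasa = burialRelSasa, probeRadius = probeRadius,
                 spherePoints = as.integer(spherePoints)),
            class = "CoreParams")
}

## quasi-uniform unit sphere points (golden-section spiral)
.spherePoints <- function(n) {
  k <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * k / n)
  theta <- pi * (1 + sqrt(5)) * k
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area
#'
#' Shrake-Rupley sphere-point SASA over the heavy atoms: each atom's solvent
#' sphere (van der Waals radius + probe) is sampled at \code{spherePoints}
#' quasi-uniform points and the accessible fraction is the fraction of
#' points outside every neighbouring atom's solvent sphere.  Per-atom areas
#' are summed per residue; relative SASA divides by a per-residue
#' theoretical maximum (\code{\link{maxSasaReference}}).
#'
#' @param structure a \linkS4class{ProteinStructure}.
#' @param params a \code{\link{coreParams}}.
#' @return list: \code{atoms} (data.frame with per-atom \code{area}),
#'   \code{residues} (data.frame resIndex, chain, resno, insert, aa1,
#'   \code{abs_sasa}, \code{rel_sasa}; rel_sasa NA for residues without a
#'   reference value and flagged when above 1.2).
#' @export
sasa <- function(structure, params = coreParams()) {
  a <- atomTable(structure)
  heavy <- which(a$isHeavy)
  if (length(heavy) == 0L) stop("no heavy atoms")
  xyz <- as.matrix(a[heavy, c("x", "y", "z")])
  rad <- vdwRadius(a$element[heavy]) + params$probeRadius
  pts <- .spherePoints(params$spherePoints)
  nH <- length(heavy)
  area <- numeric(nH)
  for (i in seq_len(nH)) {
    ## neighbours whose solvent spheres can clip atom i's sphere
    d2 <- rowSums(sweep(xyz, 2, xyz[i, ])^2)
    nb <- which(d2 < (rad + rad[i])^2 & seq_len(nH) != i)
    p <- sweep(pts * rad[i], 2, xyz[i, ], `+`)
    acc <- rep(TRUE, nrow(p))
    for (j in nb) {
      acc[acc] <- rowSums(sweep(p[acc, , drop = FALSE], 2, xyz[j, ])^2) >
        rad[j]^2
      if (!any(acc)) break
    }
    area[i] <- 4 * pi * rad[i]^2 * sum(acc) / params$spherePoints
  }
  atoms <- a
  atoms$area <- 0
  atoms$area[heavy] <- area
  rt <- residueTable(structure)
  idx <- atomResidueIndex(structure)
  absSasa <- vapply(rt$resIndex, function(k) sum(atoms$area[idx == k]),
                    numeric(1))
  ref <- maxSasaReference(rt$aa1)
  rel <- absSasa / ref
  res <- cbind(rt, abs_sasa = absSasa, rel_sasa = rel,
               rel_overshoot = !is.na(rel) & rel > 1.2)
  list(atoms = atoms, residues = res)
}

#' Buried (solvent-inaccessible) residues
#'
#' @param sasaResult result of \code{\link{sasa}}.
#' @param burialThreshold relative-SASA ceiling (default 0.10).
#' @return the residue rows with relative SASA below the threshold.
#' @export
buriedCore <- function(sasaResult, burialThreshold = 0.10) {
  res <- sasaResult$residues
  res[!is.na(res$rel_sasa) & res$rel_sasa < burialThreshold, , drop = FALSE]
}
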