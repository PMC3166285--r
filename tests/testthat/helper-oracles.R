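## Independent oracles used across the suite.  Each is deliberately coded
## with a different method than the implementation it checks.

## Horn's quaternion absolute-orientation method: an independent route to
## the least-squares superposition RMSD (checks the SVD-based Kabsch fit).
quaternionRmsd <- function(ref, mov) {
  A <- sweep(as.matrix(ref), 2, colMeans(ref))
  B <- sweep(as.matrix(mov), 2, colMeans(mov))
  M <- crossprod(B, A)  # sum over points of b a^T
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  N <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,      -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,      -Sxx - Syy + Szz),
    4, 4, byrow = TRUE)
  lmax <- max(eigen(N, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(A^2) + sum(B^2) - 2 * lmax) / nrow(A)
  sqrt(max(msd, 0))
}

## brute-force double loop over all heavy-atom pairs: residue-pair minimum
## distances across two residue-index sets
bruteMinResidueDistance <- function(struct, riA, riB) {
  a <- atomTable(struct)
  ridx <- ringscan:::atomResidueIndex(struct)
  best <- Inf
  for (i in which(ridx == riA & a$isHeavy))
    for (j in which(ridx == riB & a$isHeavy)) {
      d <- sqrt((a$x[i] - a$x[j])^2 + (a$y[i] - a$y[j])^2 +
                  (a$z[i] - a$z[j])^2)
      if (d < best) best <- d
    }
  best
}

## brute-force contact extraction: full residue-pair scan, no vectorisation
bruteContacts <- function(struct, chainA, chainB, contactCutoff = 4.0,
                          closeCutoff = 3.5) {
  rt <- residueTable(struct)
  riA <- rt$resIndex[rt$chain == chainA]
  riB <- rt$resIndex[rt$chain == chainB]
  out <- NULL
  for (ra in riA) for (rb in riB) {
    d <- bruteMinResidueDistance(struct, ra, rb)
    if (d <= contactCutoff)
      out <- rbind(out, data.frame(
        e3_resIndex = ra, e2_resIndex = rb, min_distance = d,
        tier = if (d <= closeCutoff) "close" else "contact"))
  }
  out
}

## brute-force hydrophobic neighbours of one residue
bruteHydrophobicNeighbors <- function(struct, ri, cutoff = 4.0) {
  rt <- residueTable(struct)
  hydro <- c("W", "F", "Y", "M", "L", "I", "V", "A", "C", "T", "H")
  q <- rt[rt$resIndex == ri, ]
  hits <- integer(0)
  for (rj in rt$resIndex) {
    if (rj == ri) next
    row <- rt[rt$resIndex == rj, ]
    if (!(row$aa1 %in% hydro)) next
    if (row$chain == q$chain && abs(row$resno - q$resno) == 1L) next
    if (bruteMinResidueDistance(struct, ri, rj) <= cutoff)
      hits <- c(hits, rj)
  }
  hits
}

## SCR oracle: a column belongs to a conserved region iff it lies inside
## some gap-free window of size w whose mean is at or below the threshold;
## segments are the maximal runs of such columns (length >= minLen).
coverageScrs <- function(vals, w = 3L, threshold = 3.0, minLen = 3L) {
  n <- length(vals)
  covered <- rep(FALSE, n)
  if (n >= w) for (s in 1:(n - w + 1L)) {
    win <- vals[s:(s + w - 1L)]
    if (all(!is.na(win)) && mean(win) <= threshold)
      covered[s:(s + w - 1L)] <- TRUE
  }
  r <- rle(covered)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= minLen
  data.frame(start_col = starts[keep], end_col = ends[keep])
}

## rule-table oracle: RING type from 8 ligand letters via pattern strings
ruleTableOracle <- function(letters8) {
  s <- paste(toupper(letters8), collapse = "")
  if (grepl("[^CHDGST]", s)) return("unclassified")
  if (s == "CCCHCCCC") return("C3HC4")
  if (s == "CCCHHCCC") return("C3H2C3")
  if (s == "CCCHCCCD") return("C3HC3D")
  if (s == "CCCCHCCC") return("C4HC3")
  if (s == "CCCHGCCC") return("C3HGC3")
  if (s == "CCCCCCCC") return("C4C4")
  if (s == "CCCHDCCC") return("RING-D")
  if (grepl("^C[CST]CHC[CST]CC$", s)) return("RING-S/T")
  "unclassified"
}

## vectorised variant over a matrix of letters (same logic, string route)
ruleTableOracleMatrix <- function(m) {
  s <- do.call(paste0, as.data.frame(m))
  out <- rep("unclassified", length(s))
  out[s == "CCCHCCCC"] <- "C3HC4"
  out[s == "CCCHHCCC"] <- "C3H2C3"
  out[s == "CCCHCCCD"] <- "C3HC3D"
  out[s == "CCCCHCCC"] <- "C4HC3"
  out[s == "CCCHGCCC"] <- "C3HGC3"
  out[s == "CCCCCCCC"] <- "C4C4"
  out[s == "CCCHDCCC"] <- "RING-D"
  st <- grepl("^C[CST]CHC[CST]CC$", s) & s != "CCCHCCCC"
  out[st] <- "RING-S/T"
  out[grepl("[^CHDGST]", s)] <- "unclassified"
  out
}

## is `a` a subsequence of `b`?  (independent architecture-diff check)
isSubsequence <- function(a, b) {
  i <- 1L
  for (x in b) {
    if (i <= length(a) && identical(a[i], x)) i <- i + 1L
  }
  i > length(a)
}

## build a small ProteinStructure from an atom spec data.frame
makeStructure <- function(df, id = "test") {
  defaults <- data.frame(chain = "A", resno = 1L, insert = "", resid = "ALA",
                         elety = "CA", element = "C", x = 0, y = 0, z = 0,
                         occ = 1, altloc = "", stringsAsFactors = FALSE)
  for (nm in names(defaults)) if (is.null(df[[nm]])) df[[nm]] <- defaults[[nm]]
  df$aa1 <- aaThreeToOne(df$resid)
  df$isHeavy <- !(df$element %in% c("H", "D"))
  new("ProteinStructure", id = id, modelIndex = 1, atoms = df)
}

## random rigid motion applied to an n x 3 matrix
randomRigidMotion <- function(X) {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  R <- matrix(c(
    1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[1] * q[4]),
    2 * (q[2] * q[4] + q[1] * q[3]),
    2 * (q[2] * q[3] + q[1] * q[4]), 1 - 2 * (q[2]^2 + q[4]^2),
    2 * (q[3] * q[4] - q[1] * q[2]),
    2 * (q[2] * q[4] - q[1] * q[3]), 2 * (q[3] * q[4] + q[1] * q[2]),
    1 - 2 * (q[2]^2 + q[3]^2)), 3, 3, byrow = TRUE)
  t <- rnorm(3, sd = 20)
  sweep(as.matrix(X) %*% t(R), 2, -t)
}

rigidlyMoveStructure <- function(struct) {
  a <- atomTable(struct)
  xyz <- randomRigidMotion(as.matrix(a[, c("x", "y", "z")]))
  a$x <- xyz[, 1]; a$y <- xyz[, 2]; a$z <- xyz[, 3]
  new("ProteinStructure", id = struct@id, modelIndex = struct@modelIndex,
      atoms = a)
}
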