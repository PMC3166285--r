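## Superposition, per-column RMSD and SCR detection.

test_that("identical coordinate sets superpose with zero rmsd and identity rotation", {
  set.seed(1)
  X <- matrix(rnorm(30, sd = 5), 10, 3)
  sup <- kabschSuperpose(X, X)
  expect_lt(sup@rmsd, 1e-10)
  expect_equal(sup@rotation, diag(3), tolerance = 1e-8)
})

test_that("rigid-motion copies superpose to rmsd below 1e-8", {
  set.seed(2)
  for (i in 1:20) {
    X <- matrix(rnorm(3 * sample(4:30, 1), sd = 8), ncol = 3)
    Y <- randomRigidMotion(X)
    expect_lt(kabschSuperpose(X, Y)@rmsd, 1e-8)
    ## and the fitted coordinates coincide
    sup <- kabschSuperpose(X, Y)
    expect_equal(applySuperposition(sup, Y), X, tolerance = 1e-7,
                 ignore_attr = TRUE)
  }
})

test_that("Kabsch rmsd equals the quaternion-method oracle on random pairs", {
  set.seed(3)
  for (i in 1:100) {
    n <- sample(4:40, 1)
    X <- matrix(rnorm(3 * n, sd = 6), ncol = 3)
    Y <- X + matrix(rnorm(3 * n, sd = runif(1, 0.1, 3)), ncol = 3)
    expect_equal(kabschSuperpose(X, Y)@rmsd, quaternionRmsd(X, Y),
                 tolerance = 1e-9)
  }
})

test_that("degenerate superposition inputs error instead of returning NaN", {
  expect_error(kabschSuperpose(matrix(0, 2, 3), matrix(0, 2, 3)), "3")
  line <- cbind(1:5, 0, 0)
  expect_error(kabschSuperpose(line, line), "collinear")
})

test_that("pairwise C-alpha rmsd is zero on self and symmetric", {
  plan <- data.frame(length = 12, sigma = 1.0)
  ens <- genEnsemble(plan, n = 3, seed = 12)
  s1 <- ens$structures[[1]]; s2 <- ens$structures[[2]]
  aln <- ens$alignment
  expect_equal(pairwiseCalphaRmsd(s1, s1, aln), 0, tolerance = 1e-10)
  expect_equal(pairwiseCalphaRmsd(s1, s2, aln),
               pairwiseCalphaRmsd(s2, s1, aln), tolerance = 1e-9)
})

test_that("pairwise rmsd equals an independent fit on the emitted coordinates", {
  plan <- data.frame(length = 20, sigma = 0.8)
  ens <- genEnsemble(plan, n = 2, seed = 13)
  A <- caCoords(ens$structures[[1]])
  B <- caCoords(ens$structures[[2]])
  expect_equal(pairwiseCalphaRmsd(ens$structures[[1]], ens$structures[[2]],
                                  ens$alignment),
               quaternionRmsd(A, B), tolerance = 1e-9)
})

test_that("column rmsd is zero for identical structures and matches the single-displacement closed form", {
  plan <- data.frame(length = 10, sigma = 0)
  ens <- genEnsemble(plan, n = 5, seed = 14)
  prof <- columnRmsdProfile(ens$structures, ens$alignment)
  expect_equal(unname(prof@rmsd), rep(0, 10), tolerance = 1e-9)
  ## displace one structure's column 4 by d without refitting: build
  ## structures whose other columns coincide so the fit is exact
  n <- 6; d <- 2.5
  base <- ens$structures[[1]]
  structs <- lapply(seq_len(n), function(i) {
    a <- atomTable(base)
    if (i == 1) a$z[4] <- a$z[4] + d
    new("ProteinStructure", id = sprintf("m%d", i), modelIndex = 1, atoms = a)
  })
  aln <- msAlignment(rep(strrep("A", 10), n), sprintf("m%d", seq_len(n)))
  prof2 <- columnRmsdProfile(structs, aln, referenceId = "m2",
                             superpose = FALSE)
  expect_equal(unname(prof2@rmsd[4]), d * sqrt(n - 1) / n, tolerance = 1e-6)
  expect_equal(unname(prof2@rmsd[-4]), rep(0, 9), tolerance = 1e-6)
})

test_that("column rmsd matches direct recomputation from emitted coordinates", {
  plan <- data.frame(length = c(6, 5, 7), sigma = c(0.2, 2.5, 0.2))
  ens <- genEnsemble(plan, n = 8, seed = 15)
  prof <- columnRmsdProfile(ens$structures, ens$alignment)
  ## independent recomputation: superpose with the quaternion-free route
  ## (exhaustive per-column centroids after bio3d's own fit onto member 1)
  ref <- caCoords(ens$structures[[1]])
  placed <- lapply(ens$structures, function(s) {
    xyz <- caCoords(s)
    fit <- suppressWarnings(
      bio3d::fit.xyz(as.numeric(t(ref)), as.numeric(t(xyz))))
    matrix(fit, ncol = 3, byrow = TRUE)
  })
  want <- vapply(seq_len(nrow(ref)), function(j) {
    P <- t(vapply(placed, function(m) m[j, ], numeric(3)))
    ctr <- colMeans(P)
    sqrt(mean(rowSums(sweep(P, 2, ctr)^2)))
  }, numeric(1))
  expect_equal(unname(prof@rmsd), want, tolerance = 1e-6)
})

test_that("gap columns and missing C-alpha columns stay undefined", {
  plan <- data.frame(length = 8, sigma = 0.3)
  ens <- genEnsemble(plan, n = 3, seed = 16)
  rows <- c("AAAA-AAAA", "AAAAAAAA-", "AAAA-AAAA")
  ## row 1/3 have a gap at column 5; row 2 at column 9: residues re-mapped
  aln <- msAlignment(rows, vapply(ens$structures, function(s) s@id, ""))
  prof <- columnRmsdProfile(ens$structures, aln)
  expect_true(prof@hasGap[5])
  expect_true(prof@hasGap[9])
  expect_true(is.na(prof@rmsd[5]))
})

test_that("an all-zero gap-free profile yields one full-span segment", {
  segs <- detectScrs(rep(0, 20))
  expect_equal(nrow(segs), 1L)
  expect_equal(segs$start_col, 1L)
  expect_equal(segs$end_col, 20L)
  expect_equal(segs$mean_rmsd, 0)
})

test_that("the threshold boundary is inclusive", {
  segs <- detectScrs(c(2.9, 2.9, 3.2))
  expect_equal(nrow(segs), 1L)
  expect_equal(segs$start_col, 1L)
  expect_equal(segs$end_col, 3L)
  ## one tick above the boundary fails the seed
  expect_equal(nrow(detectScrs(c(2.9, 2.9, 3.21))), 0L)
})

test_that("planted low-noise regions are detected at their boundaries", {
  plan <- data.frame(length = c(9, 6, 7, 5, 13, 5, 6),
                     sigma = c(0.3, 4, 0.3, 4, 0.3, 4, 0.3))
  ens <- genEnsemble(plan, n = 10, seed = 17)
  prof <- columnRmsdProfile(ens$structures, ens$alignment)
  segs <- detectScrs(prof)
  expect_equal(nrow(segs), 4L)
  truthStart <- ens$truth$start_col[ens$truth$sigma < 1]
  truthEnd <- ens$truth$end_col[ens$truth$sigma < 1]
  expect_true(all(abs(segs$start_col - truthStart) <= 1))
  expect_true(all(abs(segs$end_col - truthEnd) <= 1))
})

test_that("detected segments equal the window-coverage oracle on random profiles", {
  set.seed(18)
  for (i in 1:200) {
    n <- sample(10:60, 1)
    vals <- runif(n, 0, 6)
    vals[sample(n, size = rbinom(1, 3, 0.5))] <- NA  # occasional gap columns
    got <- detectScrs(vals)
    want <- coverageScrs(vals)
    expect_equal(got$start_col, want$start_col)
    expect_equal(got$end_col, want$end_col)
  }
})

test_that("coverage is monotone in the threshold", {
  set.seed(19)
  for (i in 1:50) {
    vals <- runif(40, 0, 6)
    lo <- detectScrs(vals, scrParams(threshold = 2.0))
    hi <- detectScrs(vals, scrParams(threshold = 3.0))
    coveredLo <- unlist(mapply(seq, lo$start_col, lo$end_col,
                               SIMPLIFY = FALSE))
    coveredHi <- unlist(mapply(seq, hi$start_col, hi$end_col,
                               SIMPLIFY = FALSE))
    expect_true(all(coveredLo %in% coveredHi))
  }
})

test_that("summarizeScr is the arithmetic mean and labels follow region order", {
  vals <- c(0.5, 1.0, 1.5, 9, 9, 9, 0.2, 0.2, 0.2)
  segs <- detectScrs(vals)
  expect_equal(summarizeScr(segs[1, ], vals), 1.0)
  expect_equal(summarizeScr(segs[2, ], vals), 0.2)
  lab <- labelScrRegions(segs, labels = c("N-loop", "C-loop"))
  expect_equal(lab$region_label, c("N-loop", "C-loop"))
  expect_warning(labelScrRegions(segs), "expected 4")
})

test_that("superposition rmsd is invariant under rigid motion of either input", {
  set.seed(20)
  X <- matrix(rnorm(36, sd = 5), 12, 3)
  Y <- X + matrix(rnorm(36, sd = 0.8), 12, 3)
  base <- kabschSuperpose(X, Y)@rmsd
  for (i in 1:10) {
    expect_equal(kabschSuperpose(randomRigidMotion(X), Y)@rmsd, base,
                 tolerance = 1e-9)
    expect_equal(kabschSuperpose(X, randomRigidMotion(Y))@rmsd, base,
                 tolerance = 1e-9)
  }
})
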