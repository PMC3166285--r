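## Column consensus, conservation index, equivalent-residue roles.

alnOfColumns <- function(cols) {
  ## cols: list of character vectors (one per column), all same length
  m <- do.call(cbind, cols)
  msAlignment(apply(m, 1, paste, collapse = ""),
              sprintf("r%02d", seq_len(nrow(m))))
}

test_that("identity, class and no-consensus columns call as specified", {
  aln <- alnOfColumns(list(
    rep("C", 10),
    c(rep("I", 5), rep("V", 3), rep("L", 2)),
    c(rep("K", 5), rep("R", 3), "H", "D"),
    sample(c("A","C","D","E","F","G","H","I","K","L"))))
  p1 <- columnProfile(aln, 1)
  expect_equal(p1$consensus_symbol, "C")
  expect_equal(p1$consensus_level, 1.0)
  p2 <- columnProfile(aln, 2)
  expect_equal(p2$consensus_symbol, "l")
  expect_equal(p2$consensus_level, 1.0)
  p3 <- columnProfile(aln, 3)
  expect_equal(p3$consensus_symbol, "+")
  expect_equal(p3$consensus_level, 0.9)
  p4 <- columnProfile(aln, 4)
  expect_true(is.na(p4$consensus_symbol) || p4$consensus_level < 0.8)
})

test_that("gap handling: non-gap denominator, all-gap columns stay silent", {
  aln <- msAlignment(c("C-", "C-", "--"), c("a", "b", "c"))
  p1 <- columnProfile(aln, 1)
  expect_equal(p1$n_nongap, 2L)
  expect_equal(p1$consensus_symbol, "C")
  expect_false(p1$low_support)  # 2 of 3 rows is at least half
  aln3 <- msAlignment(c("C", "-", "-"), c("a", "b", "c"))
  expect_true(columnProfile(aln3, 1)$low_support)
  p2 <- columnProfile(aln, 2)
  expect_equal(p2$n_nongap, 0L)
  expect_true(is.na(p2$consensus_symbol))
  expect_equal(p2$conservation_index, 0L)
})

test_that("conservation index matches hand-computed entropies", {
  one <- c(C = 1)
  expect_equal(conservationIndex(one, 1), 9L)
  unif <- rep(1 / 20, 20)
  names(unif) <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  expect_equal(conservationIndex(unif, 20), 0L)
  ## {C: 0.8, S: 0.2}: H = 0.50040, Hmax = ln 20 = 2.99573 -> index 7
  mix <- c(C = 0.8, S = 0.2)
  H <- -(0.8 * log(0.8) + 0.2 * log(0.2))
  expect_equal(floor(9 * (1 - H / log(20)) + 0.5), 7)
  expect_equal(conservationIndex(mix, 10), 7L)
})

test_that("conservation index is monotone non-increasing in entropy", {
  set.seed(11)
  pairs <- replicate(50, {
    k1 <- sample(1:20, 1); k2 <- sample(1:20, 1)
    f1 <- runif(k1); f1 <- f1 / sum(f1)
    f2 <- runif(k2); f2 <- f2 / sum(f2)
    H1 <- -sum(f1 * log(f1)); H2 <- -sum(f2 * log(f2))
    names(f1) <- sample(names(ringscan::maxSasaReference()), k1)
    names(f2) <- sample(names(ringscan::maxSasaReference()), k2)
    i1 <- conservationIndex(f1, 10); i2 <- conservationIndex(f2, 10)
    if (H1 <= H2) i1 >= i2 else i2 >= i1
  })
  expect_true(all(pairs))
})

test_that("consensus level is row-permutation invariant and grows with duplicates", {
  set.seed(3)
  col <- c(rep("I", 6), rep("V", 2), "K", "E")
  for (i in 1:5) {
    aln <- alnOfColumns(list(sample(col)))
    p <- columnProfile(aln, 1)
    expect_equal(p$consensus_symbol, "l")
    expect_equal(p$consensus_level, 0.8)
  }
  ## duplicating a row that carries the consensus class never lowers it
  aln2 <- alnOfColumns(list(c(col, "I")))
  expect_gte(columnProfile(aln2, 1)$consensus_level, 0.8)
})

test_that("called conserved columns on a planted alignment are exactly the plant", {
  planted <- data.frame(column = c(5, 12, 18, 25, 33, 40),
                        class = c("h", "h", "h", "h", "p", "p"),
                        level = 0.9)
  g <- genMsa(30, 46, planted, seed = 5)
  called <- callConservedColumns(g$alignment)
  expect_equal(called$called_columns, planted$column)
})

test_that("identical sequences make every ungapped column conserved", {
  aln <- msAlignment(rep("MKVLDEKF", 6), sprintf("s%d", 1:6))
  called <- callConservedColumns(aln)
  expect_equal(called$called_columns, 1:8)
  expect_equal(called$ligand_columns, integer(0))
  ## invariant Cys/His columns are split out as ligand columns
  aln2 <- msAlignment(rep("MCVHDEKF", 6), sprintf("s%d", 1:6))
  called2 <- callConservedColumns(aln2)
  expect_equal(called2$ligand_columns, c(2L, 4L))
  expect_equal(called2$called_columns, c(1L, 3L, 5:8))
})

test_that("unattainable thresholds call nothing", {
  aln <- msAlignment(rep("MKVLDEKF", 6), sprintf("s%d", 1:6))
  called <- callConservedColumns(aln, levelThreshold = 1.01,
                                 indexThreshold = 10)
  expect_equal(called$called_columns, integer(0))
})

test_that("equivalent-residue roles map planted columns by region", {
  planted <- data.frame(column = c(3, 16, 20, 28, 18, 30),
                        class = c("h", "h", "h", "h", "p", "p"),
                        level = 0.95)
  g <- genMsa(24, 34, planted, seed = 8)
  scr <- data.frame(start_col = c(1, 8, 14, 26), end_col = c(6, 12, 24, 32),
                    region_label = c("N-loop", "beta", "beta-alpha", "C-loop"),
                    stringsAsFactors = FALSE)
  res <- assignEquivalentResidues(g$alignment, planted$column, scr)
  roles <- res$roles
  expect_equal(roles$column[roles$role == "hydro1"], 3)
  expect_equal(sort(roles$column[roles$role %in% c("hydro2", "hydro3")]),
               c(16, 20))
  expect_equal(roles$column[roles$role == "hydro4"], 28)
  expect_equal(roles$column[roles$role == "polar1"], 18)
  expect_equal(roles$column[roles$role == "polar2"], 30)
  expect_length(res$diagnostics, 0)
  ## per-sequence residue indices agree with the column maps
  expect_equal(res$per_sequence$hydro1,
               unname(vapply(alignmentIds(g$alignment), function(id)
                 columnMap(g$alignment, id)[3], integer(1))))
})

test_that("Pro identity and positive-class columns are accepted in their roles", {
  ## C-loop hydro role occupied by invariant Pro; C-loop polar role by K/R
  cols <- list(
    c(rep("L", 9), "V"),            # 1 N-loop hydro
    c(rep("I", 9), "L"),            # 2 beta-alpha hydro
    c(rep("F", 9), "Y"),            # 3 beta-alpha hydro
    c(rep("E", 9), "D"),            # 4 beta-alpha polar (negative)
    rep("P", 10),                   # 5 C-loop hydro: Pro identity
    c(rep("R", 5), rep("K", 4), "H"))  # 6 C-loop polar: positive class
  aln <- alnOfColumns(cols)
  scr <- data.frame(start_col = c(1, 2, 5), end_col = c(1, 4, 6),
                    region_label = c("N-loop", "beta-alpha", "C-loop"),
                    stringsAsFactors = FALSE)
  res <- assignEquivalentResidues(aln, 1:6, scr)
  roles <- res$roles
  expect_equal(roles$column[roles$role == "hydro4"], 5)
  expect_equal(roles$consensus_symbol[roles$role == "hydro4"], "P")
  expect_equal(roles$column[roles$role == "polar2"], 6)
  expect_equal(roles$consensus_symbol[roles$role == "polar2"], "+")
})

test_that("missing role columns surface as diagnostics, not silently", {
  cols <- list(c(rep("L", 9), "V"))
  aln <- alnOfColumns(cols)
  scr <- data.frame(start_col = 1, end_col = 1, region_label = "N-loop",
                    stringsAsFactors = FALSE)
  res <- assignEquivalentResidues(aln, 1, scr)
  expect_true(any(grepl("beta-alpha", res$diagnostics)))
  expect_true(any(grepl("C-loop", res$diagnostics)))
})
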