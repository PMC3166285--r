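## Tiered interface contacts, backbone hydrogen bonds, region assignment.

twoChainStructure <- function(dfA, dfB) {
  dfA$chain <- "A"; dfB$chain <- "B"
  makeStructure(rbind(dfA, dfB), id = "complex")
}

test_that("chains far apart produce no contacts", {
  s <- twoChainStructure(data.frame(resno = 1:3, x = c(0, 4, 8), y = 0, z = 0),
                         data.frame(resno = 1:3, x = c(0, 4, 8), y = 50, z = 0))
  expect_equal(nrow(extractContacts(s, "A", "B")), 0L)
})

test_that("planted pair distances land in the right tiers", {
  d <- c(2.9, 3.0, 3.2, 3.4, 3.5, 3.7, 3.9, 4.0, 4.5, 6.0)
  cx <- genComplex(d, seed = 40)
  rec <- extractContacts(cx$structure, "A", "B")
  expect_equal(nrow(rec), 8L)                 # pairs at <= 4.0
  expect_equal(sum(rec$tier == "close"), 5L)  # pairs at <= 3.5
  expect_equal(countCloseE3Residues(rec), 5L)
  ## distances reproduce the plan exactly (planted residues are single atoms)
  expect_equal(sort(rec$min_distance), sort(d[d <= 4.0]), tolerance = 1e-9)
  ## boundary: exactly 4.0 is a contact, exactly 3.5 is close
  expect_true(any(abs(rec$min_distance - 4.0) < 1e-9 & rec$tier == "contact"))
  expect_true(any(abs(rec$min_distance - 3.5) < 1e-9 & rec$tier == "close"))
})

test_that("swapping the selections mirrors the records with identical distances", {
  cx <- genComplex(c(3.0, 3.8, 5.0), seed = 41)
  ab <- extractContacts(cx$structure, "A", "B")
  ba <- extractContacts(cx$structure, "B", "A")
  expect_equal(nrow(ab), nrow(ba))
  key1 <- paste(ab$e3_resno, ab$e2_resno, round(ab$min_distance, 6))
  key2 <- paste(ba$e2_resno, ba$e3_resno, round(ba$min_distance, 6))
  expect_setequal(key1, key2)
})

test_that("empty or overlapping selections error", {
  cx <- genComplex(c(3.0), seed = 42)
  expect_error(extractContacts(cx$structure, "Z", "B"), "empty")
  expect_error(extractContacts(cx$structure, "A", "A"), "overlap")
})

test_that("contact extraction equals the brute-force all-pair scan", {
  set.seed(43)
  for (rep in 1:20) {
    nA <- sample(4:10, 1); nB <- sample(4:10, 1)
    dfA <- data.frame(resno = seq_len(nA), x = runif(nA, 0, 15),
                      y = runif(nA, 0, 15), z = runif(nA, 0, 15))
    dfB <- data.frame(resno = seq_len(nB), x = runif(nB, 0, 15),
                      y = runif(nB, 0, 15), z = runif(nB, 0, 15))
    s <- twoChainStructure(dfA, dfB)
    got <- extractContacts(s, "A", "B")
    want <- bruteContacts(s, "A", "B")
    if (is.null(want)) {
      expect_equal(nrow(got), 0L)
    } else {
      want <- want[order(want$e3_resIndex, want$min_distance), ]
      expect_equal(got$e3_resIndex, want$e3_resIndex)
      expect_equal(got$e2_resIndex, want$e2_resIndex)
      expect_equal(got$min_distance, want$min_distance, tolerance = 1e-9)
      expect_equal(got$tier, want$tier)
    }
  }
})

test_that("close-tier records are always a subset of contact records", {
  set.seed(44)
  for (rep in 1:10) {
    cx <- genComplex(runif(6, 2.5, 6), seed = sample(1e6, 1))
    rec <- extractContacts(cx$structure, "A", "B")
    expect_true(all(rec$min_distance <= 4.0))
    expect_true(all(rec$min_distance[rec$tier == "close"] <= 3.5))
    expect_true(all(rec$min_distance[rec$tier == "contact"] > 3.5))
  }
})

test_that("contact counts survive rigid motion of the whole complex", {
  cx <- genComplex(c(2.9, 3.6, 4.2), seed = 45)
  base <- extractContacts(cx$structure, "A", "B")
  set.seed(46)
  for (i in 1:5) {
    moved <- rigidlyMoveStructure(cx$structure)
    rec <- extractContacts(moved, "A", "B")
    expect_equal(nrow(rec), nrow(base))
    expect_equal(rec$min_distance, base$min_distance, tolerance = 1e-8)
  }
})

test_that("backbone hydrogen bonds are distance-gated N...O cross-chain pairs", {
  dfA <- data.frame(resno = c(1L, 1L, 2L, 2L),
                    elety = c("N", "O", "N", "O"), element = c("N", "O", "N", "O"),
                    x = c(0, 1.2, 20, 21.2), y = 0, z = 0)
  dfB <- data.frame(resno = c(1L, 1L),
                    elety = c("N", "O"), element = c("N", "O"),
                    x = c(4.1, 0), y = c(0, 2.9), z = 0)
  s <- twoChainStructure(dfA, dfB)
  hb <- detectBackboneHbonds(s, "A", "B")
  ## A:1 N (0,0,0) to B O at (0,2.9,0): 2.9 A -> bond; B N at (4.1,0,0) to
  ## A O at (1.2,0,0): 2.9 A -> bond; nothing else within 3.5
  expect_equal(nrow(hb), 2L)
  expect_equal(sort(hb$distance), c(2.9, 2.9), tolerance = 1e-9)
  ## planted N...O at 3.6 A is excluded
  dfB2 <- dfB; dfB2$y[2] <- 3.6
  hb2 <- detectBackboneHbonds(twoChainStructure(dfA, dfB2), "A", "B")
  expect_equal(nrow(hb2), 1L)
  ## far-apart chains: none
  dfB3 <- dfB; dfB3$x <- dfB3$x + 100
  expect_equal(nrow(detectBackboneHbonds(twoChainStructure(dfA, dfB3),
                                         "A", "B")), 0L)
})

test_that("contact residues are assigned to SCR regions I/II/III by column", {
  cx <- genComplex(c(3.0, 3.2, 3.8, 3.3), seed = 47)
  rec <- extractContacts(cx$structure, "A", "B")
  ## chain A residues 1..4 in contact; alignment row maps residue i -> col i
  nRes <- sum(residueTable(cx$structure)$chain == "A")
  aln <- msAlignment(rep(strrep("A", nRes), 1), "e3")
  scr <- data.frame(start_col = c(1, 2, 3, 4), end_col = c(1, 2, 3, 4),
                    region_label = c("N-loop", "beta", "beta-alpha", "C-loop"),
                    stringsAsFactors = FALSE)
  sm <- assignContactsToRegions(rec, scr, aln, "e3")
  r <- sm$residues
  expect_equal(r$region[r$e3_resIndex == 1], "I")
  expect_equal(r$region[r$e3_resIndex == 2], "none")  # beta region: no code
  expect_equal(r$region[r$e3_resIndex == 3], "II")
  expect_equal(r$region[r$e3_resIndex == 4], "III")
  expect_equal(sm$n_contact_residues_e3, 4L)
  expect_equal(sm$n_close_residues_e3, 3L)  # 3.8 A pair is contact, not close
})

test_that("residues outside every SCR are labelled none", {
  cx <- genComplex(c(3.0), seed = 48)
  rec <- extractContacts(cx$structure, "A", "B")
  nRes <- sum(residueTable(cx$structure)$chain == "A")
  aln <- msAlignment(strrep("A", nRes), "e3")
  scr <- data.frame(start_col = 50, end_col = 55, region_label = "N-loop",
                    stringsAsFactors = FALSE)
  sm <- assignContactsToRegions(rec, scr, aln, "e3")
  expect_true(all(sm$residues$region == "none"))
})

test_that("selection strings parse chain and residue ranges", {
  sel <- parseSelection("A:381-420")
  expect_equal(sel$chain, "A")
  expect_equal(sel$start, 381L)
  expect_equal(sel$end, 420L)
  expect_equal(parseSelection("B")$chain, "B")
  expect_null(parseSelection("B")$start)
})
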