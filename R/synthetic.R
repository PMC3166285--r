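## Seeded synthetic-data generators.  Every generator emits standard formats
## plus a ground-truth table so downstream stages can be tested closed-loop
## without downloads.  All randomness flows through one seed per call
## (withr::with_seed), so identical specs give identical output.

.REFERENCE_LETTERS <- list(
  "C3HC4"    = c("C", "C", "C", "H", "C", "C", "C", "C"),
  "C3H2C3"   = c("C", "C", "C", "H", "H", "C", "C", "C"),
  "C3HC3D"   = c("C", "C", "C", "H", "C", "C", "C", "D"),
  "C4HC3"    = c("C", "C", "C", "C", "H", "C", "C", "C"),
  "C3HGC3"   = c("C", "C", "C", "H", "G", "C", "C", "C"),
  "C4C4"     = c("C", "C", "C", "C", "C", "C", "C", "C"),
  "RING-D"   = c("C", "C", "C", "H", "D", "C", "C", "C"),
  "RING-S/T" = c("C", "S", "C", "H", "C", "T", "C", "C"))

## flank/spacer alphabet: no letter that can occupy a ligand position, so
## the planted pattern is the unique zero-substitution candidate
.NEUTRAL_AA <- c("A", "E", "F", "I", "K", "L", "M", "N", "P", "Q", "R", "V",
                 "W", "Y")

#' Generate sequences with planted metal-ligand patterns
#'
#' Each sequence carries one planted 8-position ligand pattern for its type,
#' at uniformly drawn admissible spacings, embedded in random flanks drawn
#' from an alphabet free of ligand-capable letters.
#'
#' @param types character vector: one entry per sequence, naming the planted
#'   type (see names of supported types in the classifier rule table;
#'   U-box is not plantable).
#' @param seed integer seed.
#' @param model spacing model used for admissible gaps.
#' @param flankRange min/max flank length on each side.
#' @return list: \code{sequences} (named character vector), \code{truth}
#'   data.frame (seq_id, type, positions comma-joined, letters).
#' @export
genRingSequences <- function(types, seed,
                             model = ligandSpacingModel(),
                             flankRange = c(5L, 20L)) {
  if (length(types) == 0L)
    return(list(sequences = character(0),
                truth = data.frame(seq_id = character(), type = character(),
                                   positions = character(),
                                   letters = character(),
                                   stringsAsFactors = FALSE)))
  bad <- setdiff(types, names(.REFERENCE_LETTERS))
  if (length(bad)) stop("unsupported planted type(s): ",
                        paste(unique(bad), collapse = ", "))
  withr::with_seed(seed, {
    seqs <- character(length(types))
    truth <- vector("list", length(types))
    for (i in seq_along(types)) {
      lets <- .REFERENCE_LETTERS[[types[i]]]
      gaps <- vapply(seq_len(7), function(k)
        sample(model$gapRanges[k, 1]:model$gapRanges[k, 2], 1L), integer(1))
      left <- sample(flankRange[1]:flankRange[2], 1L)
      right <- sample(flankRange[1]:flankRange[2], 1L)
      body <- character(0)
      pos <- integer(8)
      cur <- left
      for (k in 1:8) {
        pos[k] <- cur + 1L
        body <- c(body, lets[k])
        cur <- cur + 1L
        if (k < 8L) {
          body <- c(body, sample(.NEUTRAL_AA, gaps[k], replace = TRUE))
          cur <- cur + gaps[k]
        }
      }
      seqs[i] <- paste(c(sample(.NEUTRAL_AA, left, replace = TRUE), body,
                         sample(.NEUTRAL_AA, right, replace = TRUE)),
                       collapse = "")
      truth[[i]] <- data.frame(
        seq_id = sprintf("syn%03d", i), type = types[i],
        positions = paste(pos, collapse = ","),
        letters = paste(lets, collapse = ""), stringsAsFactors = FALSE)
    }
    names(seqs) <- sprintf("syn%03d", seq_along(types))
    list(sequences = seqs, truth = do.call(rbind, truth))
  })
}

## self-avoiding random walk with fixed step length (C-alpha trace)
.randomWalk <- function(n, step = 3.8, minSep = 3.0, maxTries = 200L) {
  xyz <- matrix(0, n, 3)
  for (i in seq_len(n)[-1]) {
    placed <- FALSE
    for (t in seq_len(maxTries)) {
      u <- stats::rnorm(3)
      u <- u / sqrt(sum(u^2))
      cand <- xyz[i - 1L, ] + step * u
      prev <- xyz[seq_len(max(i - 2L, 1L)), , drop = FALSE]
      if (i == 2L || min(sqrt(rowSums(sweep(prev, 2, cand)^2))) >= minSep) {
        xyz[i, ] <- cand; placed <- TRUE; break
      }
    }
    if (!placed) stop("self-avoiding walk failed; relax minSep")
  }
  xyz
}

.structureFromCa <- function(ca, id, chain = "A", resno = seq_len(nrow(ca)),
                             aa3 = "ALA") {
  n <- nrow(ca)
  atoms <- data.frame(
    chain = chain, resno = resno, insert = "", resid = aa3,
    aa1 = aaThreeToOne(aa3), elety = "CA", element = "C",
    x = ca[, 1], y = ca[, 2], z = ca[, 3], occ = 1, altloc = "",
    isHeavy = TRUE, stringsAsFactors = FALSE)
  new("ProteinStructure", id = id, modelIndex = 1, atoms = atoms)
}

#' Generate a superposed structure ensemble with region-wise noise
#'
#' A template C-alpha backbone (self-avoiding random walk, 3.8 Angstrom
#' steps) is perturbed per member with isotropic Gaussian noise whose
#' standard deviation is set per region, emulating a superposed ensemble
#' with structurally conserved (low sigma) and variable (high sigma)
#' stretches.  The matching alignment is columnar (no gaps).
#'
#' @param regionPlan data.frame or matrix with columns \code{length} and
#'   \code{sigma} (Angstrom), in order along the chain.
#' @param n number of ensemble members.
#' @param seed integer seed.
#' @param dir optional directory: when given, members are written as PDB
#'   files and the alignment as aligned FASTA.
#' @return list: \code{structures} (list of \linkS4class{ProteinStructure}),
#'   \code{alignment}, \code{truth} (region boundaries and sigma),
#'   \code{template} coordinates, and file paths when \code{dir} given.
#' @export
genEnsemble <- function(regionPlan, n, seed, dir = NULL) {
  plan <- as.data.frame(regionPlan)
  names(plan) <- c("length", "sigma")[seq_len(ncol(plan))]
  stopifnot(all(plan$length >= 1), all(plan$sigma >= 0), n >= 1)
  total <- sum(plan$length)
  withr::with_seed(seed, {
    template <- .randomWalk(total)
    sigmaPerCol <- rep(plan$sigma, plan$length)
    structures <- lapply(seq_len(n), function(i) {
      noise <- matrix(stats::rnorm(3 * total, sd = rep(sigmaPerCol, 3)),
                      total, 3)
      .structureFromCa(template + noise, sprintf("ens%02d", i))
    })
  })
  rows <- rep(paste(rep("A", total), collapse = ""), n)
  aln <- msAlignment(rows, vapply(structures, function(s) s@id, ""))
  ends <- cumsum(plan$length)
  truth <- data.frame(region = seq_len(nrow(plan)),
                      start_col = c(1L, utils::head(ends, -1) + 1L),
                      end_col = ends, sigma = plan$sigma)
  out <- list(structures = structures, alignment = aln, truth = truth,
              template = template)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    out$pdb_files <- vapply(structures, function(s) {
      p <- file.path(dir, paste0(s@id, ".pdb")); writeStructure(s, p); p
    }, "")
    out$alignment_file <- file.path(dir, "ensemble_aln.fasta")
    writeAlignmentFasta(aln, out$alignment_file)
    utils::write.table(truth, file.path(dir, "ensemble_truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}

#' Generate a two-chain complex with planted cross-chain distances
#'
#' Chain A (E3) and chain B (E2) are laid out so that each planned pair
#' contributes exactly one cross-chain atom pair at the planned distance,
#' while all other atoms stay at least 8 Angstrom from the other chain.
#' Planted residues carry a single atom so the pair distance is exact.
#'
#' @param distances numeric vector of planned pair distances (Angstrom).
#' @param seed integer seed.
#' @param nDecoyPerChain additional far-apart residues per chain.
#' @param contactCutoff,closeCutoff tier cutoffs recorded in the truth.
#' @return list: \code{structure} (two-chain
#'   \linkS4class{ProteinStructure}), \code{truth} data.frame (e3_resno,
#'   e2_resno, distance, expected_tier).
#' @export
genComplex <- function(distances, seed, nDecoyPerChain = 5L,
                       contactCutoff = 4.0, closeCutoff = 3.5) {
  k <- length(distances)
  withr::with_seed(seed, {
    rowsA <- list(); rowsB <- list()
    for (i in seq_len(k)) {
      x <- 20 * i
      rowsA[[i]] <- c(x, 0, 0)
      rowsB[[i]] <- c(x, distances[i], 0)
    }
    ## decoys: far behind each chain (y << 0 for A, y >> max distance for B)
    for (j in seq_len(nDecoyPerChain)) {
      rowsA[[k + j]] <- c(20 * j + stats::runif(1, -3, 3), -30 - 5 * j,
                          stats::runif(1, -3, 3))
      rowsB[[k + j]] <- c(20 * j + stats::runif(1, -3, 3), 50 + 5 * j,
                          stats::runif(1, -3, 3))
    }
  })
  mk <- function(rows, chain, offset) {
    n <- length(rows)
    data.frame(
      chain = chain, resno = seq_len(n) + offset, insert = "", resid = "ALA",
      aa1 = "A", elety = "CA", element = "C",
      x = vapply(rows, `[`, 0, 1), y = vapply(rows, `[`, 0, 2),
      z = vapply(rows, `[`, 0, 3), occ = 1, altloc = "", isHeavy = TRUE,
      stringsAsFactors = FALSE)
  }
  atoms <- rbind(mk(rowsA, "A", 0L), mk(rowsB, "B", 0L))
  struct <- new("ProteinStructure", id = "synthetic_complex", modelIndex = 1,
                atoms = atoms)
  tier <- rep(NA_character_, k)
  tier[distances <= contactCutoff] <- "contact"
  tier[distances <= closeCutoff] <- "close"
  truth <- data.frame(e3_resno = seq_len(k), e2_resno = seq_len(k),
                      distance = distances, expected_tier = tier,
                      stringsAsFactors = FALSE)
  list(structure = struct, truth = truth)
}

#' Generate an alignment with planted class-conserved columns
#'
#' Random columns draw letters uniformly from the 20 standard residues;
#' planted columns draw, with probability \code{level}, from a low-entropy
#' subset of the planted class (so both the consensus level and the
#' conservation index pass their thresholds) and otherwise from letters
#' outside the class.
#'
#' @param nRows number of sequences.
#' @param nCols total number of columns.
#' @param planted data.frame with \code{column}, \code{class} ('h' or 'p')
#'   and \code{level} (target consensus level).
#' @param seed integer seed.
#' @return list: \code{alignment}, \code{truth} (the planted table with the
#'   realised level).
#' @export
genMsa <- function(nRows, nCols, planted, seed) {
  alphabet <- residueClassAlphabet()
  classRep <- list(h = c("L", "I", "V"), p = c("K", "R"),
                   l = c("L", "I"), "+" = c("K", "R"), "-" = c("D", "E"),
                   o = c("S", "T"))
  withr::with_seed(seed, {
    m <- matrix(sample(.STANDARD_AA, nRows * nCols, replace = TRUE),
                nRows, nCols)
    realised <- numeric(nrow(planted))
    for (i in seq_len(nrow(planted))) {
      cls <- planted$class[i]
      memb <- alphabet[[cls]]
      if (is.null(memb)) stop("unknown class symbol: ", cls)
      rep <- classRep[[cls]] %||% memb
      nIn <- round(planted$level[i] * nRows)
      if (nIn > nRows) stop("unattainable level for column ", planted$column[i])
      inRows <- sample(nRows, nIn)
      col <- character(nRows)
      col[inRows] <- sample(rep, nIn, replace = TRUE)
      col[-inRows] <- sample(setdiff(.STANDARD_AA, memb), nRows - nIn,
                             replace = TRUE)
      m[, planted$column[i]] <- col
      realised[i] <- mean(col %in% memb)
    }
  })
  rows <- apply(m, 1, paste, collapse = "")
  aln <- msAlignment(rows, sprintf("row%03d", seq_len(nRows)))
  truth <- cbind(planted, realised_level = realised)
  list(alignment = aln, truth = truth)
}

#' Generate reciprocal hit tables with planted orthologs
#'
#' Proteomes \code{a1..aN} and \code{b1..bM}; the first \code{nOrtholog}
#' index pairs are planted as mutual best hits; decoy hits are strictly
#' lower-scoring cross pairs.
#'
#' @param nA,nB proteome sizes.
#' @param nOrtholog number of planted pairs (<= min(nA, nB)).
#' @param noiseRate expected decoy hits per planted hit (fraction).
#' @param seed integer seed.
#' @return list: \code{hitsAB}, \code{hitsBA} (data.frames in
#'   \code{readBlastHits} layout), \code{truth} (id_a, id_b).
#' @export
genHits <- function(nA, nB, nOrtholog, noiseRate = 0.1, seed) {
  stopifnot(nOrtholog <= min(nA, nB))
  idsA <- sprintf("a%04d", seq_len(nA))
  idsB <- sprintf("b%04d", seq_len(nB))
  withr::with_seed(seed, {
    mkDir <- function(qids, sids, planted) {
      qs <- qids[planted]; ss <- sids[planted]
      best <- data.frame(query_id = qs, subject_id = ss,
                         pct_identity = round(stats::runif(length(qs), 40, 90), 1),
                         bit_score = round(stats::runif(length(qs), 200, 500), 1),
                         e_value = 10^(-stats::runif(length(qs), 50, 120)),
                         stringsAsFactors = FALSE)
      ## decoys point at planted subjects only, so a decoy can never close a
      ## spurious reciprocal loop; scores are strictly below the planted range
      nNoise <- if (length(planted)) round(noiseRate * length(qids)) else 0L
      noise <- data.frame(
        query_id = sample(qids, nNoise, replace = TRUE),
        subject_id = sample(sids[planted], nNoise, replace = TRUE),
        pct_identity = round(stats::runif(nNoise, 20, 40), 1),
        bit_score = round(stats::runif(nNoise, 30, 150), 1),
        e_value = 10^(-stats::runif(nNoise, 2, 30)),
        stringsAsFactors = FALSE)
      out <- rbind(best, noise)
      out[sample(nrow(out)), , drop = FALSE]
    }
    hitsAB <- mkDir(idsA, idsB, seq_len(nOrtholog))
    hitsBA <- mkDir(idsB, idsA, seq_len(nOrtholog))
  })
  truth <- data.frame(id_a = idsA[seq_len(nOrtholog)],
                      id_b = idsB[seq_len(nOrtholog)],
                      stringsAsFactors = FALSE)
  list(hitsAB = hitsAB, hitsBA = hitsBA, truth = truth)
}
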