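## Reciprocal-best-hit orthology and domain-architecture comparison.

#' Best hit per query
#'
#' Ranks subjects per query by bit score, ties broken by lower e-value, then
#' higher percent identity, then lexicographic subject id.  Self hits
#' (query == subject) are removed before ranking.
#'
#' @param hits data.frame from \code{\link{readBlastHits}}.
#' @return data.frame: query_id, subject_id, bit_score, e_value,
#'   pct_identity (one row per query with at least one non-self hit).
#' @export
bestHits <- function(hits) {
  h <- hits[hits$query_id != hits$subject_id, , drop = FALSE]
  if (nrow(h) == 0L) return(h)
  ord <- order(h$query_id, -h$bit_score, h$e_value, -h$pct_identity,
               h$subject_id)
  h <- h[ord, , drop = FALSE]
  h <- h[!duplicated(h$query_id), , drop = FALSE]
  rownames(h) <- NULL
  h
}

#' Reciprocal best hits
#'
#' Ortholog pairs: a and b are returned when a's best hit is b and b's best
#' hit is a.  Output sorted by \code{id_a}.
#'
#' @param hitsAB hits of proteome A queried against proteome B.
#' @param hitsBA hits of proteome B queried against proteome A.
#' @return data.frame: id_a, id_b, score_ab, score_ba, evalue_ab, evalue_ba.
#' @export
rbbh <- function(hitsAB, hitsBA) {
  ab <- bestHits(hitsAB)
  ba <- bestHits(hitsBA)
  back <- structure(ba$subject_id, names = ba$query_id)
  keep <- !is.na(back[ab$subject_id]) & back[ab$subject_id] == ab$query_id
  keep[is.na(keep)] <- FALSE
  ab <- ab[keep, , drop = FALSE]
  i <- match(ab$subject_id, ba$query_id)
  out <- data.frame(id_a = ab$query_id, id_b = ab$subject_id,
                    score_ab = ab$bit_score, score_ba = ba$bit_score[i],
                    evalue_ab = ab$e_value, evalue_ba = ba$e_value[i],
                    stringsAsFactors = FALSE)
  out <- out[order(out$id_a), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## longest common subsequence of two character vectors; returns the index
## pairs of one (leftmost-biased) optimal embedding
.lcsIndices <- function(a, b) {
  n <- length(a); m <- length(b)
  L <- matrix(0L, n + 1L, m + 1L)
  for (i in seq_len(n)) for (j in seq_len(m))
    L[i + 1L, j + 1L] <- if (a[i] == b[j]) L[i, j] + 1L else
      max(L[i, j + 1L], L[i + 1L, j])
  ia <- integer(0); ib <- integer(0)
  i <- n; j <- m
  while (i > 0L && j > 0L) {
    if (a[i] == b[j] && L[i + 1L, j + 1L] == L[i, j] + 1L) {
      ia <- c(i, ia); ib <- c(j, ib); i <- i - 1L; j <- j - 1L
    } else if (L[i, j + 1L] >= L[i + 1L, j]) i <- i - 1L else j <- j - 1L
  }
  list(a = ia, b = ib)
}

#' Compare two ordered domain architectures
#'
#' Classifies the relation between two ordered domain-name lists:
#' \code{identical}; \code{insertion} when the first list is a strict
#' subsequence of the second (extra domains gained); \code{deletion} for the
#' converse; \code{rearrangement} when the name multisets are equal but the
#' order differs; \code{other} otherwise.  Inserted/deleted domains are
#' reported with their positions on the longer list (via a longest common
#' subsequence embedding).
#'
#' @param archA,archB character vectors of domain names in sequence order
#'   (e.g. from \code{\link{architectureOf}}).
#' @return list: relation, inserted (data.frame name/position), deleted.
#' @export
compareArchitectures <- function(archA, archB) {
  stopifnot(length(archA) > 0L, length(archB) > 0L)
  empty <- data.frame(name = character(), position = integer(),
                      stringsAsFactors = FALSE)
  if (identical(archA, archB))
    return(list(relation = "identical", inserted = empty, deleted = empty))
  lcs <- .lcsIndices(archA, archB)
  if (length(lcs$a) == length(archA) && length(archA) < length(archB)) {
    pos <- setdiff(seq_along(archB), lcs$b)
    return(list(relation = "insertion",
                inserted = data.frame(name = archB[pos], position = pos,
                                      stringsAsFactors = FALSE),
                deleted = empty))
  }
  if (length(lcs$b) == length(archB) && length(archB) < length(archA)) {
    pos <- setdiff(seq_along(archA), lcs$a)
    return(list(relation = "deletion", inserted = empty,
                deleted = data.frame(name = archA[pos], position = pos,
                                     stringsAsFactors = FALSE)))
  }
  if (identical(sort(archA), sort(archB)))
    return(list(relation = "rearrangement", inserted = empty, deleted = empty))
  list(relation = "other", inserted = empty, deleted = empty)
}
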