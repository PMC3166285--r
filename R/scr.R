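## Structurally conserved region (SCR) detection.
##
## An SCR is a run of at least min_len gap-free alignment columns whose
## per-column C-alpha RMSD from the ensemble centroid stays low: a sliding
## window of size w seeds a segment wherever its mean RMSD is at or below
## the threshold, the segment grows rightward while the trailing w-window
## keeps qualifying, and qualifying segments that touch are merged.  See the
## methods vignette for why extension tracks the trailing window rather than
## the cumulative mean.

#' SCR detection parameters
#'
#' @param window sliding window size w (default 3).
#' @param threshold mean-RMSD ceiling in Angstrom (default 3.0; 2.0 is the
#'   stricter preset used to describe region cores).
#' @param minLen minimum segment length (default 3).
#' @return list with class \code{ScrParams}.
#' @export
scrParams <- function(window = 3L, threshold = 3.0, minLen = 3L) {
  stopifnot(window >= 1L, threshold > 0, minLen >= 1L)
  structure(list(window = as.integer(window), threshold = threshold,
                 minLen = as.integer(minLen)), class = "ScrParams")
}

#' Detect structurally conserved regions
#'
#' Scans all window start positions: a window of \code{w} consecutive
#' gap-free columns with mean RMSD at or below the threshold qualifies
#' (boundary inclusive).  Every maximal run of qualifying window starts
#' yields a segment spanning the union of its windows; segments that
#' overlap or are adjacent are merged, and segments shorter than
#' \code{minLen} are discarded.  Scanning every start makes the result
#' order-independent.
#'
#' @param profile a \linkS4class{ColumnRmsdProfile}, or a numeric vector of
#'   per-column RMSD values with NA at gap columns.
#' @param params a \code{\link{scrParams}}.
#' @return data.frame: start_col, end_col, length, mean_rmsd, region_label
#'   (NA until \code{\link{labelScrRegions}}), sorted by start, pairwise
#'   non-overlapping.
#' @export
detectScrs <- function(profile, params = scrParams()) {
  vals <- if (is(profile, "ColumnRmsdProfile")) profile@rmsd else as.numeric(profile)
  w <- params$window
  n <- length(vals)
  empty <- data.frame(start_col = integer(), end_col = integer(),
                      length = integer(), mean_rmsd = numeric(),
                      region_label = character(), stringsAsFactors = FALSE)
  if (n < w) return(empty)
  ok <- !is.na(vals)
  ## qualifying window start positions
  qual <- vapply(seq_len(n - w + 1L), function(s) {
    win <- vals[s:(s + w - 1L)]
    all(!is.na(win)) && mean(win) <= params$threshold
  }, logical(1))
  if (!any(qual)) return(empty)
  ## segments: per qualifying seed, extend while the trailing window stays
  ## qualifying; then merge overlapping/adjacent segments
  segs <- list()
  for (s in which(qual)) {
    e <- s + w - 1L
    t <- s + 1L
    while (t <= n - w + 1L && qual[t]) {
      e <- t + w - 1L
      t <- t + 1L
    }
    segs[[length(segs) + 1L]] <- c(s, e)
  }
  segs <- do.call(rbind, segs)
  segs <- segs[order(segs[, 1]), , drop = FALSE]
  merged <- list(segs[1, ])
  for (i in seq_len(nrow(segs))[-1]) {
    last <- merged[[length(merged)]]
    if (segs[i, 1] <= last[2] + 1L)
      merged[[length(merged)]] <- c(last[1], max(last[2], segs[i, 2]))
    else merged[[length(merged) + 1L]] <- segs[i, ]
  }
  out <- do.call(rbind, merged)
  keep <- (out[, 2] - out[, 1] + 1L) >= params$minLen
  out <- out[keep, , drop = FALSE]
  if (nrow(out) == 0L) return(empty)
  data.frame(
    start_col = out[, 1], end_col = out[, 2],
    length = out[, 2] - out[, 1] + 1L,
    mean_rmsd = vapply(seq_len(nrow(out)), function(i)
      mean(vals[out[i, 1]:out[i, 2]]), numeric(1)),
    region_label = NA_character_, stringsAsFactors = FALSE)
}

#' Mean RMSD over a segment
#' @param segment one row of a \code{\link{detectScrs}} result (or a list
#'   with start_col/end_col).
#' @param profile a \linkS4class{ColumnRmsdProfile} or numeric vector.
#' @return arithmetic mean RMSD over the segment's columns.
#' @export
summarizeScr <- function(segment, profile) {
  vals <- if (is(profile, "ColumnRmsdProfile")) profile@rmsd else as.numeric(profile)
  mean(vals[segment$start_col:segment$end_col])
}

#' Label SCR segments with their region roles
#'
#' The RING fold carries four SCRs in sequence order: N-loop, the first
#' beta-sheet region, the beta-alpha region and the C-loop.  When the number
#' of detected segments equals the number of labels they are assigned in
#' order; otherwise labels stay NA and a warning reports the mismatch.
#'
#' @param segments data.frame from \code{\link{detectScrs}}.
#' @param labels region labels in order.
#' @return the segments with \code{region_label} filled in.
#' @export
labelScrRegions <- function(segments,
                            labels = c("N-loop", "beta", "beta-alpha", "C-loop")) {
  if (nrow(segments) == length(labels)) {
    segments$region_label <- labels
  } else if (nrow(segments) > 0) {
    warning("expected ", length(labels), " segments, found ", nrow(segments),
            "; region labels left NA")
  }
  segments
}
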