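## Tabular inputs: BLAST tabular hit tables and domain-architecture tables.

#' Read a BLAST tabular (outfmt 6) hit table
#'
#' Expects the standard 12-column dialect; only query id, subject id, percent
#' identity, bit score and e-value are consumed, the remaining columns are
#' ignored.  Row order is preserved.
#'
#' @param path tab-separated file, no header.
#' @return data.frame with columns \code{query_id}, \code{subject_id},
#'   \code{pct_identity}, \code{bit_score}, \code{e_value}.
#' @export
readBlastHits <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (nrow(raw) == 0L)
    return(data.frame(query_id = character(), subject_id = character(),
                      pct_identity = numeric(), bit_score = numeric(),
                      e_value = numeric(), stringsAsFactors = FALSE))
  if (ncol(raw) != 12L)
    stop("expected 12 tab-separated columns, found ", ncol(raw), " in ", path)
  num <- function(v, what) {
    out <- suppressWarnings(as.numeric(v))
    if (anyNA(out)) stop("unparsable ", what, " value in ", path, ": ",
                         v[which(is.na(out))[1L]])
    out
  }
  hits <- data.frame(
    query_id = raw[[1L]], subject_id = raw[[2L]],
    pct_identity = num(raw[[3L]], "percent-identity"),
    bit_score = num(raw[[12L]], "bit-score"),
    e_value = num(raw[[11L]], "e-value"),
    stringsAsFactors = FALSE)
  if (any(hits$pct_identity < 0 | hits$pct_identity > 100))
    stop("percent identity outside [0, 100] in ", path)
  if (any(hits$e_value < 0)) stop("negative e-value in ", path)
  hits
}

#' Write a hit table in BLAST tabular layout
#'
#' Unconsumed columns are filled with zeros.
#'
#' @param hits data.frame as returned by \code{readBlastHits}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeBlastHits <- function(hits, path) {
  n <- nrow(hits)
  tab <- data.frame(
    hits$query_id, hits$subject_id,
    formatC(hits$pct_identity, format = "f", digits = 2),
    rep(0L, n), rep(0L, n), rep(0L, n), rep(0L, n), rep(0L, n),
    rep(0L, n), rep(0L, n),
    formatC(hits$e_value, format = "g", digits = 3),
    formatC(hits$bit_score, format = "f", digits = 1),
    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a domain-architecture table
#'
#' @param path TSV with header columns \code{protein_id}, \code{domain},
#'   \code{start}, \code{end} (1-based inclusive).
#' @return data.frame sorted by protein then start; validated (start <= end,
#'   no duplicate identical intervals within a protein).
#' @export
readDomainArchitectures <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "domain", "start", "end")
  if (!all(need %in% names(d)))
    stop("architecture table must have columns ", paste(need, collapse = ", "))
  d$start <- as.integer(d$start); d$end <- as.integer(d$end)
  if (any(d$start > d$end)) stop("domain interval with start > end in ", path)
  d <- d[order(d$protein_id, d$start, d$end), , drop = FALSE]
  key <- paste(d$protein_id, d$domain, d$start, d$end)
  if (anyDuplicated(key)) stop("duplicate identical domain interval in ", path)
  rownames(d) <- NULL
  d
}

#' Ordered domain-name list of one protein
#' @param arch data.frame from \code{readDomainArchitectures}.
#' @param proteinId protein id.
#' @return character vector of domain names in sequence order.
#' @export
architectureOf <- function(arch, proteinId) {
  d <- arch[arch$protein_id == proteinId, , drop = FALSE]
  if (nrow(d) == 0L) stop("no domains for protein '", proteinId, "'")
  d$domain[order(d$start, d$end)]
}
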