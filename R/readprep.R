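#' Collapse sequence-identical reads
#'
#' PCR duplicates in CRAC libraries are removed by collapsing reads with
#' identical sequence; the multiplicity is retained as a `count` column so
#' downstream steps can optionally weight by it (the default throughout the
#' package is one count per unique read, which is conservative for PCR
#' duplicates).  Output order is the order of first occurrence.
#'
#' @param reads Data.frame with columns `id`, `seq`.
#' @return Data.frame with columns `id` (first occurrence), `seq`, `count`.
#' @export
collapse_duplicates <- function(reads) {
  if (nrow(reads) == 0L) {
    return(data.frame(id = character(0), seq = character(0), count = integer(0),
                      stringsAsFactors = FALSE))
  }
  first <- !duplicated(reads$seq)
  counts <- table(factor(reads$seq, levels = reads$seq[first]))
  data.frame(id = reads$id[first], seq = reads$seq[first],
             count = as.integer(counts), stringsAsFactors = FALSE)
}

#' Trim the 3' sequencing adapter
#'
#' Removes the longest read suffix that matches a prefix of the adapter with
#' at least `min_overlap` nt and at most one mismatch; reads shorter than
#' `min_length` after trimming are discarded.
#'
#' @param reads Data.frame with columns `id`, `seq` (and optionally `count`).
#' @param adapter Adapter sequence (non-empty).
#' @param min_overlap Minimum matched adapter prefix length.
#' @param min_length Minimum retained read length after trimming.
#' @param max_mismatch Mismatches tolerated in the adapter match (use 0 for
#'   error-free libraries; 1, the default, for sequencing-error tolerance).
#' @return The reads table with trimmed `seq`; discarded reads are dropped
#'   and their number stored in attribute `n_discarded`.
#' @export
trim_adapter <- function(reads, adapter, min_overlap = 5L, min_length = 15L,
                         max_mismatch = 1L) {
  stopifnot(nchar(adapter) >= 1L)
  if (nrow(reads) == 0L) {
    out <- reads
    attr(out, "n_discarded") <- 0L
    return(out)
  }
  keep_len <- trim_adapter_cpp(reads$seq, adapter, as.integer(min_overlap),
                               as.integer(max_mismatch))
  out <- reads
  out$seq <- substr(reads$seq, 1L, keep_len)
  ok <- nchar(out$seq) >= min_length
  res <- out[ok, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "n_discarded") <- sum(!ok)
  res
}
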