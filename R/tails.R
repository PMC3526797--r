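#' Call non-templated 3' oligo(A) tails
#'
#' For every mapped alignment the 3' soft clip is first re-extended against
#' the downstream reference (in transcript orientation): any soft-clip prefix
#' matching the reference is templated and moved back into the aligned span.
#' The remaining suffix is the candidate tail; a read is called A-tailed when
#' the tail is at least `min_A` nt long and composed of adenosines (at the
#' required purity, 1 by default).  A genomic A immediately downstream is
#' therefore absorbed as templated -- a deliberate, conservative bias that
#' undercounts tails in A-rich contexts.
#'
#' @param alignments A `crac_alignments` table in genomic coordinates.
#' @param genome A `crac_genome`.
#' @param min_A Minimum tail length (and adenosine count) to call a tail.
#' @param purity Minimum fraction of A in the tail (1 = strict all-A rule).
#' @param adapter Optional adapter sequence: an exact terminal match between
#'   a suffix of the (post-extension) soft clip and a prefix of the adapter
#'   is removed before tail classification, handling adapter read-through
#'   too short for overlap-based trimming.
#' @return List with `alignments` (re-extended; `start`/`cigar`/`soft3`
#'   updated) and `tails`, a data.frame with columns `read_id`, `tail`,
#'   `n_A`, `a_tailed` and `first_A_coord` (0-based genomic coordinate where
#'   the first non-templated adenosine sits, defined only for A-tailed
#'   reads: the transcript-strand 3' end of the aligned span).
#' @export
call_tails <- function(alignments, genome, min_A = 2L, purity = 1,
                       adapter = NULL) {
  n <- nrow(alignments)
  tail <- character(n); n_A <- integer(n)
  a_tailed <- logical(n); firstA <- rep(NA_integer_, n)
  out <- alignments
  ends <- aln_end(alignments)
  cand <- which(nzchar(alignments$soft3))
  for (i in cand) {
    s3 <- alignments$soft3[i]
    ls <- nchar(s3)
    chrom <- alignments$chrom[i]
    clen <- genome$lengths[[chrom]]
    if (alignments$strand[i] == "+") {
      avail <- min(ls, clen - ends[i])
      down <- if (avail > 0L) {
        genome_seq(genome, chrom, ends[i], ends[i] + avail)
      } else ""
    } else {
      avail <- min(ls, alignments$start[i])
      down <- if (avail > 0L) {
        revcomp(genome_seq(genome, chrom, alignments$start[i] - avail,
                           alignments$start[i]))
      } else ""
    }
    j <- 0L
    while (j < avail && substr(s3, j + 1L, j + 1L) == substr(down, j + 1L, j + 1L)) {
      j <- j + 1L
    }
    if (j > 0L) { # absorb templated prefix into the aligned span
      o <- cigar_ops(alignments$cigar[i])[[1L]]
      if (alignments$strand[i] == "+") {
        si <- nrow(o)
        stopifnot(o$op[si] == "S")
        o$len[si] <- o$len[si] - j
        mi <- si - 1L
        if (mi >= 1L && o$op[mi] == "M") o$len[mi] <- o$len[mi] + j else {
          o <- rbind(o[seq_len(si - 1L), ], data.frame(len = j, op = "M"),
                     o[si, ])
        }
        o <- o[o$len > 0L, , drop = FALSE]
        ends[i] <- ends[i] + j
      } else {
        si <- 1L
        stopifnot(o$op[si] == "S")
        o$len[si] <- o$len[si] - j
        if (nrow(o) >= 2L && o$op[2L] == "M") o$len[2L] <- o$len[2L] + j else {
          o <- rbind(o[1L, ], data.frame(len = j, op = "M"),
                     o[-1L, ])
        }
        o <- o[o$len > 0L, , drop = FALSE]
        out$start[i] <- alignments$start[i] - j
      }
      out$cigar[i] <- paste0(o$len, o$op, collapse = "")
      out$soft3[i] <- substr(s3, j + 1L, ls)
    }
    tl <- substr(s3, j + 1L, ls)
    if (!is.null(adapter) && nzchar(tl)) {
      # strip terminal adapter read-through too short for overlap trimming
      for (al in seq.int(min(nchar(tl), nchar(adapter)), 1L)) {
        if (substr(tl, nchar(tl) - al + 1L, nchar(tl)) == substr(adapter, 1L, al)) {
          tl <- substr(tl, 1L, nchar(tl) - al)
          break
        }
      }
    }
    tail[i] <- tl
    na <- sum(strsplit(tl, "")[[1L]] == "A")
    n_A[i] <- na
    a_tailed[i] <- nchar(tl) >= min_A && na >= min_A &&
      (nchar(tl) == 0L || na / nchar(tl) >= purity)
    if (a_tailed[i]) {
      firstA[i] <- if (alignments$strand[i] == "+") ends[i] else out$start[i] - 1L
    }
  }
  tails <- data.frame(read_id = alignments$read_id, tail = tail, n_A = n_A,
                      a_tailed = a_tailed, first_A_coord = firstA,
                      stringsAsFactors = FALSE)
  list(alignments = out, tails = tails)
}

#' Extract microdeletion positions from alignments
#'
#' Walks each CIGAR accumulating the 0-based genomic coordinates covered by
#' D operations.  Multi-nt deletions contribute one position per deleted
#' base, matching per-base deletion-track rendering.
#'
#' @param alignments A `crac_alignments` table.
#' @return Data.frame with columns `read_id`, `pos` (sorted within read),
#'   one row per deleted reference base.
#' @export
extract_deletions <- function(alignments) {
  ops <- cigar_ops(alignments$cigar)
  ids <- list(); poss <- list()
  for (i in seq_along(ops)) {
    o <- ops[[i]]
    pos <- alignments$start[i]
    dp <- integer(0)
    for (j in seq_len(nrow(o))) {
      if (o$op[j] == "D") dp <- c(dp, seq.int(pos, pos + o$len[j] - 1L))
      if (o$op[j] %in% c("M", "D", "N")) pos <- pos + o$len[j]
    }
    if (length(dp)) {
      ids[[length(ids) + 1L]] <- rep(alignments$read_id[i], length(dp))
      poss[[length(poss) + 1L]] <- sort(dp)
    }
  }
  data.frame(read_id = unlist(ids) %||% character(0),
             pos = unlist(poss) %||% integer(0), stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Filter alignments to A-tailed reads
#'
#' @param alignments A `crac_alignments` table.
#' @param tails Tail-call table from [call_tails()].
#' @return The subset of `alignments` whose reads are A-tailed, in the
#'   original order.
#' @export
filter_a_tailed <- function(alignments, tails) {
  m <- match(alignments$read_id, tails$read_id)
  if (anyNA(m)) {
    stop("missing tail call for ", sum(is.na(m)), " alignment(s)")
  }
  out <- alignments[tails$a_tailed[m], , drop = FALSE]
  rownames(out) <- NULL
  out
}
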