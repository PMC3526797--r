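#' Align reads to the genome and splice-junction library
#'
#' Desk-scale seed-and-extend aligner: the read's 5'-most k-mer is matched
#' exactly against both strands of the genome and against exon-exon junction
#' entries, then extended 3'-ward by banded edit alignment allowing
#' mismatches and 1-3 nt reference deletions (match +1, mismatch -2, gap -3).
#' Trailing unextendable bases become a 3' soft clip, so non-templated tails
#' survive alignment.  Ties are broken by the lowest (reference, coordinate);
#' reads with more than one distinct best locus are flagged `multi` and
#' excluded from counting by default.
#'
#' @param reads Data.frame with columns `id`, `seq` and optionally `count`.
#' @param genome A `crac_genome`.
#' @param junctions Optional `crac_junctions` table; its EE entries are added
#'   as (plus-strand-only) alignment references.
#' @param seed_length Exact-match seed length (read 5'-most k-mer).
#' @param max_del_total Maximum total deleted reference nt per read.
#' @param max_del_event Maximum length of a single deletion event.
#' @param match,mismatch,gap Alignment scores (gap is the per-event penalty).
#' @return A `crac_alignments` data.frame with one row per mapped read:
#'   `read_id`, `chrom` (chromosome or junction entry name), `strand`,
#'   `start` (0-based), `cigar` (forward-reference order, `S` only at ends),
#'   `score`, `count`, `multi`, `soft3` (the read's 3' soft-clipped
#'   sequence), `origin` (`"genome"` or `"junction"`).  Unmapped read counts
#'   are recorded in attribute `n_unmapped`.
#' @export
align_reads <- function(reads, genome, junctions = NULL,
                        seed_length = 12L, max_del_total = 6L,
                        max_del_event = 3L, match = 1L, mismatch = -2L,
                        gap = 3L) {
  ref_names <- names(genome$seq)
  ref_seqs <- unname(genome$seq)
  allow_rc <- rep(TRUE, length(ref_seqs))
  origin <- rep("genome", length(ref_seqs))
  boundary <- rep(-1L, length(ref_seqs))
  if (!is.null(junctions) && nrow(junctions) > 0L) {
    ee <- junctions[junctions$kind == "EE", , drop = FALSE]
    if (nrow(ee) > 0L) {
      ref_names <- c(ref_names, junction_names(ee))
      ref_seqs <- c(ref_seqs, ee$seq)
      allow_rc <- c(allow_rc, rep(FALSE, nrow(ee)))
      origin <- c(origin, rep("junction", nrow(ee)))
      # junction alignments must cross the splice boundary to count as loci
      boundary <- c(boundary, ee$flank_up)
    }
  }
  res <- align_reads_cpp(reads$seq, ref_seqs, allow_rc, boundary,
                         k = as.integer(seed_length),
                         max_del_total = as.integer(max_del_total),
                         max_del_event = as.integer(max_del_event),
                         match = as.integer(match),
                         mismatch = as.integer(mismatch),
                         gap_pen = as.integer(gap))
  mapped <- res$mapped
  cnt <- if ("count" %in% names(reads)) reads$count else rep(1L, nrow(reads))
  clip3 <- res$clip3[mapped]
  seqs <- reads$seq[mapped]
  out <- data.frame(
    read_id = reads$id[mapped],
    chrom = ref_names[res$ref[mapped]],
    strand = res$strand[mapped],
    start = res$start[mapped],
    cigar = res$cigar[mapped],
    score = res$score[mapped],
    count = cnt[mapped],
    multi = res$n_best[mapped] > 1L,
    soft3 = ifelse(clip3 > 0L, substr(seqs, nchar(seqs) - clip3 + 1L, nchar(seqs)), ""),
    origin = origin[res$ref[mapped]],
    stringsAsFactors = FALSE
  )
  class(out) <- c("crac_alignments", "data.frame")
  attr(out, "n_unmapped") <- sum(!mapped)
  out
}

#' Parse CIGAR strings into op lists
#'
#' @param cigar Character vector of CIGAR strings (ops M, I, D, N, S).
#' @return List of data.frames with columns `len`, `op`.
#' @export
cigar_ops <- function(cigar) {
  lapply(regmatches(cigar, gregexpr("\\d+[MIDNS]", cigar)), function(x) {
    data.frame(len = as.integer(sub("[MIDNS]$", "", x)),
               op = sub("^\\d+", "", x), stringsAsFactors = FALSE)
  })
}

#' Reference span of CIGAR strings (sum of M, D and N lengths)
#'
#' @param cigar Character vector of CIGAR strings.
#' @return Integer vector of spans in nt.
#' @export
cigar_ref_span <- function(cigar) {
  vapply(cigar_ops(cigar), function(o) {
    sum(o$len[o$op %in% c("M", "D", "N")])
  }, integer(1))
}

#' Alignment end coordinates (0-based exclusive)
#'
#' @param alignments A `crac_alignments` table.
#' @return Integer vector `start + reference span`.
#' @export
aln_end <- function(alignments) {
  alignments$start + cigar_ref_span(alignments$cigar)
}

#' Aligned (M) reference segments of each alignment
#'
#' @param alignments A `crac_alignments` table.
#' @return Data.frame with columns `row` (alignment row index), `start`,
#'   `end` (0-based half-open genomic intervals covered by M ops).
#' @export
aln_m_segments <- function(alignments) {
  ops <- cigar_ops(alignments$cigar)
  n_per <- vapply(ops, function(o) sum(o$op == "M"), integer(1))
  row <- rep(seq_len(nrow(alignments)), n_per)
  starts <- integer(sum(n_per)); ends <- integer(sum(n_per))
  k <- 0L
  for (i in seq_along(ops)) {
    pos <- alignments$start[i]
    o <- ops[[i]]
    for (j in seq_len(nrow(o))) {
      if (o$op[j] == "M") {
        k <- k + 1L
        starts[k] <- pos; ends[k] <- pos + o$len[j]
      }
      if (o$op[j] %in% c("M", "D", "N")) pos <- pos + o$len[j]
    }
  }
  data.frame(row = row, start = starts, end = ends)
}

#' Lift junction-entry alignments to genomic coordinates
#'
#' Alignments against exon-exon junction entries are mapped back onto the
#' genome as spliced alignments (`M-N-M`), preserving deletions; genomic
#' alignments pass through unchanged.  Junction metadata (`junc_feature`,
#' `junc_kind`, `junc_off`, `junc_flank_up`) is retained for junction
#' counting.
#'
#' @param alignments A `crac_alignments` table from [align_reads()].
#' @param junctions The `crac_junctions` table used for alignment.
#' @param features The `crac_features` table.
#' @return A `crac_alignments` table in genomic coordinates.
#' @export
lift_junction_alignments <- function(alignments, junctions, features) {
  out <- alignments
  out$junc_feature <- NA_character_
  out$junc_kind <- NA_character_
  out$junc_off <- NA_integer_
  out$junc_flank_up <- NA_integer_
  jrows <- which(alignments$origin == "junction")
  if (!length(jrows)) return(out)
  jname <- junction_names(junctions)
  for (i in jrows) {
    j <- match(alignments$chrom[i], jname)
    if (is.na(j)) stop("unknown junction reference: ", alignments$chrom[i])
    jj <- junctions[j, ]
    f <- features[match(jj$feature, features$id), ]
    mat_map <- template_map(f, "mature")
    entry_start_mat <- jj$mat_anchor - jj$flank_up # mature coord of entry base 0
    ops <- cigar_ops(alignments$cigar[i])[[1L]]
    # walk ops in entry space collecting per-op genomic positions
    gpos <- list(); pos <- alignments$start[i]
    for (r in seq_len(nrow(ops))) {
      if (ops$op[r] %in% c("M", "D")) {
        mats <- entry_start_mat + seq.int(pos, pos + ops$len[r] - 1L)
        gpos[[r]] <- mat_map[mats + 1L]
        pos <- pos + ops$len[r]
      } else gpos[[r]] <- integer(0)
    }
    # rebuild genomic cigar: contiguous runs of consecutive genomic positions
    segs <- list()
    for (r in seq_len(nrow(ops))) {
      g <- gpos[[r]]
      if (!length(g)) { segs[[length(segs) + 1L]] <- list(op = ops$op[r], g = g); next }
      if (f$strand == "-") g <- sort(g)
      br <- c(0L, which(diff(g) != 1L), length(g))
      for (b in seq_len(length(br) - 1L)) {
        segs[[length(segs) + 1L]] <- list(op = ops$op[r],
                                          g = g[(br[b] + 1L):br[b + 1L]])
      }
    }
    # order segments by genomic coordinate and insert N gaps
    keep <- vapply(segs, function(s) length(s$g) > 0L || s$op == "S", logical(1))
    segs <- segs[keep]
    gmin <- vapply(segs, function(s) if (length(s$g)) min(s$g) else NA_integer_, integer(1))
    ord <- order(is.na(gmin), gmin)
    s_lead <- segs[vapply(segs, function(s) s$op == "S", logical(1))]
    segs <- segs[ord[!is.na(gmin[ord])]]
    cig <- character(0); prev_end <- NA_integer_
    for (s in segs) {
      st <- min(s$g); en <- max(s$g) + 1L
      if (!is.na(prev_end) && st > prev_end) {
        cig <- c(cig, sprintf("%dN", st - prev_end))
      }
      cig <- c(cig, sprintf("%d%s", en - st, s$op))
      prev_end <- en
    }
    new_start <- min(vapply(segs, function(s) min(s$g), integer(1)))
    # soft clip placement: read 3' end is genomic right on +, left on -
    sclip <- if (length(s_lead)) {
      op0 <- cigar_ops(alignments$cigar[i])[[1L]]
      sl <- op0$len[op0$op == "S"]
      sprintf("%dS", sl[1L])
    } else NULL
    strand <- f$strand
    full_cig <- if (is.null(sclip)) paste(cig, collapse = "") else {
      if (strand == "+") paste(c(cig, sclip), collapse = "") else
        paste(c(sclip, cig), collapse = "")
    }
    out$chrom[i] <- f$chrom
    out$strand[i] <- strand
    out$start[i] <- new_start
    out$cigar[i] <- full_cig
    out$junc_feature[i] <- jj$feature
    out$junc_kind[i] <- jj$kind
    out$junc_off[i] <- alignments$start[i]
    out$junc_flank_up[i] <- jj$flank_up
  }
  out
}

#' Exhaustive single-gap alignment oracle
#'
#' Independent reference scorer used to validate the seed-and-extend
#' aligner: enumerates every start position on both strands of a (small)
#' genome, every single reference-deletion placement (length 1-3 at any
#' read position) and every 3' soft-clip length, under the same scoring
#' scheme (match +1, mismatch -2, gap -3), and returns the optimal score.
#' Complexity is O(genome x read x gap placements); intended for references
#' of a few kb.
#'
#' @param read Read sequence.
#' @param genome A `crac_genome`.
#' @param match,mismatch,gap Scores.
#' @param max_del_event Maximum single-deletion length.
#' @return Best achievable score (integer).
#' @export
oracle_align_score <- function(read, genome, match = 1L, mismatch = -2L,
                               gap = 3L, max_del_event = 3L) {
  oracle_align_cpp(read, unname(genome$seq), match, mismatch, gap,
                   max_del_event)[1L]
}

#' Vectorized form of [oracle_align_score()]
#'
#' @param reads Character vector of read sequences.
#' @inheritParams oracle_align_score
#' @return Integer vector of best scores.
#' @export
oracle_align_scores <- function(reads, genome, match = 1L, mismatch = -2L,
                                gap = 3L, max_del_event = 3L) {
  oracle_align_cpp(reads, unname(genome$seq), match, mismatch, gap,
                   max_del_event)
}
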