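#' Build the splice-junction reference library
#'
#' For every intron of every spliced feature, three entries are generated in
#' transcript orientation: the exon-exon junction (`EE`, present only in the
#' spliced mRNA), and the two intron-exon boundaries of the unspliced
#' precursor (`IE5` at the 5' splice site, `IE3` at the 3' splice site).
#' `EE` entries carry the spliced flanking sequence and serve as additional
#' alignment references for junction-spanning reads; `IE` entries lie on the
#' contiguous genomic sequence and provide boundary anchors for counting.
#'
#' @param features A `crac_features` table.
#' @param genome A `crac_genome`.
#' @param flank Flank length in nt on each side of the junction.
#' @return A `data.frame` of class `crac_junctions` with columns `feature`,
#'   `kind`, `chrom`, `strand`, `coord` (genomic cut point: the boundary lies
#'   between forward-strand positions `coord - 1` and `coord`, anchored at the
#'   transcript-5' side of the intron for EE entries), `intron` (index in
#'   transcript order), `seq`, `flank_up`, `flank_down`, `truncated`, and for
#'   EE entries `mat_anchor` (0-based mature-transcript coordinate of the
#'   junction).  The requested flank is stored as attribute `flank`.
#' @export
build_junction_library <- function(features, genome, flank = 50L) {
  stopifnot(flank >= 1L)
  rows <- list()
  for (i in seq_len(nrow(features))) {
    f <- features[i, ]
    e <- f$exons[[1L]]
    if (nrow(e) < 2L) next
    mat <- feature_sequence(genome, f, "mature")
    pre <- feature_sequence(genome, f, "precursor")
    ex_tx <- if (f$strand == "+") e else e[nrow(e):1L, , drop = FALSE]
    exlen <- ex_tx[, 2L] - ex_tx[, 1L]
    intron_tx <- if (f$strand == "+") feature_introns(f) else {
      ii <- feature_introns(f); ii[nrow(ii):1L, , drop = FALSE]
    }
    inlen <- intron_tx[, 2L] - intron_tx[, 1L]
    cum_mat <- cumsum(exlen)
    cum_pre <- cumsum(exlen + c(inlen, 0L)) # precursor coord at end of exon j + intron j
    for (j in seq_len(nrow(intron_tx))) {
      fu_ee <- min(flank, exlen[j]); fd_ee <- min(flank, exlen[j + 1L])
      c_mat <- cum_mat[j]
      ee_seq <- substr(mat, c_mat - fu_ee + 1L, c_mat + fd_ee)
      c5 <- if (j == 1L) exlen[1L] else cum_pre[j - 1L] + exlen[j]
      c3 <- c5 + inlen[j]
      fu_5 <- min(flank, exlen[j]); fd_5 <- min(flank, inlen[j])
      fu_3 <- min(flank, inlen[j]); fd_3 <- min(flank, exlen[j + 1L])
      ie5_seq <- substr(pre, c5 - fu_5 + 1L, c5 + fd_5)
      ie3_seq <- substr(pre, c3 - fu_3 + 1L, c3 + fd_3)
      if (f$strand == "+") {
        co5 <- intron_tx[j, 1L]; co3 <- intron_tx[j, 2L]; coee <- intron_tx[j, 1L]
      } else {
        co5 <- intron_tx[j, 2L]; co3 <- intron_tx[j, 1L]; coee <- intron_tx[j, 2L]
      }
      rows[[length(rows) + 1L]] <- data.frame(
        feature = f$id, kind = c("EE", "IE5", "IE3"),
        chrom = f$chrom, strand = f$strand,
        coord = c(coee, co5, co3), intron = j,
        seq = c(ee_seq, ie5_seq, ie3_seq),
        flank_up = c(fu_ee, fu_5, fu_3), flank_down = c(fd_ee, fd_5, fd_3),
        truncated = c(fu_ee < flank || fd_ee < flank,
                      fu_5 < flank || fd_5 < flank,
                      fu_3 < flank || fd_3 < flank),
        mat_anchor = c(c_mat, NA_integer_, NA_integer_),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    feature = character(0), kind = character(0), chrom = character(0),
    strand = character(0), coord = integer(0), intron = integer(0),
    seq = character(0), flank_up = integer(0), flank_down = integer(0),
    truncated = logical(0), mat_anchor = integer(0), stringsAsFactors = FALSE)
  attr(out, "flank") <- as.integer(flank)
  class(out) <- c("crac_junctions", "data.frame")
  out
}

#' Name of a junction entry as used in FASTA export and as alignment reference
#' @param junctions A `crac_junctions` table (or subset).
#' @return Character vector `"feature|kind|coord"`.
#' @export
junction_names <- function(junctions) {
  sprintf("%s|%s|%d", junctions$feature, junctions$kind, junctions$coord)
}

#' Write the junction library as FASTA
#'
#' Record names follow the structured form `feature|kind|coord` so alignments
#' to junction entries can be mapped back to genomic coordinates.
#'
#' @param junctions A `crac_junctions` table.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_junction_fasta <- function(junctions, path) {
  ss <- Biostrings::DNAStringSet(junctions$seq)
  names(ss) <- junction_names(junctions)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
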