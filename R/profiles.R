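#' Per-base coverage track (hits or deletions) in hpm
#'
#' Hit tracks add the per-read hpm weight to every reference base covered by
#' an M operation (D/N gaps are not covered); deletion tracks add the weight
#' to every deleted reference base, so the deletion density indexes the
#' crosslinked nucleotide itself.
#'
#' @param alignments A `crac_alignments` table in genomic coordinates.
#' @param genome A `crac_genome`.
#' @param chrom Chromosome to profile.
#' @param kind `"hits"` or `"dels"`.
#' @param filter `"total"` or `"a_tailed"` (requires `tails`).
#' @param tails Tail-call table, required for the A-tailed filter.
#' @param strand `"+"`, `"-"` or `"both"`.
#' @param total_mapped Library size for hpm normalization; defaults to the
#'   number of counted alignments in `alignments`.
#' @return A list of class `crac_track`: `chrom`, `strand`, `kind`,
#'   `filter`, `values` (numeric vector over the chromosome, hpm).
#' @export
pileup <- function(alignments, genome, chrom,
                   kind = c("hits", "dels"), filter = c("total", "a_tailed"),
                   tails = NULL, strand = "both", total_mapped = NULL) {
  kind <- match.arg(kind); filter <- match.arg(filter)
  clen <- unname(genome$lengths[chrom])
  if (is.na(clen)) stop("region outside genome: unknown chromosome ", chrom)
  aln <- alignments[!alignments$multi, , drop = FALSE]
  if (is.null(total_mapped)) total_mapped <- nrow(aln)
  if (filter == "a_tailed") {
    if (is.null(tails)) stop("a_tailed filter requires tail calls")
    aln <- filter_a_tailed(aln, tails)
  }
  sel <- aln$chrom == chrom
  if (strand != "both") sel <- sel & aln$strand == strand
  aln <- aln[sel, , drop = FALSE]
  w <- if (total_mapped > 0L) 1e6 / total_mapped else 0
  vals <- numeric(clen)
  if (nrow(aln) > 0L) {
    if (kind == "hits") {
      seg <- aln_m_segments(aln)
      cov <- IRanges::coverage(IRanges::IRanges(seg$start + 1L, seg$end),
                               width = clen)
      vals <- as.numeric(cov) * w
    } else {
      dels <- extract_deletions(aln)
      if (nrow(dels) > 0L) {
        tb <- tabulate(dels$pos + 1L, nbins = clen)
        vals <- tb * w
      }
    }
  }
  structure(list(chrom = chrom, strand = strand, kind = kind, filter = filter,
                 values = vals), class = "crac_track")
}

#' Coverage profile of a single RNA in transcript orientation
#'
#' Extracts a feature's window (with flanks) from a strand-matched coverage
#' track, reversed for minus-strand features so position 0 is the feature's
#' 5' end.
#'
#' @param track A `crac_track` (strand-specific, matching the feature).
#' @param feature One row of a `crac_features` table.
#' @param flank Flank width in nt on both sides.
#' @return Numeric vector of length `span + 2*flank`, named by position
#'   relative to the feature 5' end (flank positions negative).
#' @export
rna_profile <- function(track, feature, flank = 0L) {
  lo <- feature$start - flank; hi <- feature$end + flank
  clen <- length(track$values)
  pos <- seq.int(lo, hi - 1L)
  v <- rep(NA_real_, length(pos))
  ok <- pos >= 0L & pos < clen
  v[ok] <- track$values[pos[ok] + 1L]
  if (feature$strand == "-") v <- rev(v)
  names(v) <- seq_along(v) - flank - 1L
  v
}

#' 3' splice-site anchored pre-mRNA metagene
#'
#' Builds a genes x positions coverage matrix for spliced mRNAs, each row
#' aligned at the 3' splice site of its (first, transcript-order) intron and
#' ordered by intron length, descending.  Values are raw hpm (no per-gene
#' normalization) so expression differences remain visible; use
#' `row_normalize = TRUE` for a per-gene display export.
#'
#' @param alignments A `crac_alignments` table in genomic coordinates.
#' @param genome A `crac_genome`.
#' @param features A `crac_features` table.
#' @param window Integer (upstream, downstream) window around the anchor in
#'   nt (transcript orientation).
#' @param row_normalize Divide each row by its maximum (rows with all-zero
#'   coverage are left as zeros).
#' @param total_mapped Library size for hpm weights.
#' @return List with `matrix` (rows named by gene, columns by position
#'   relative to the 3'SS; position 0 is the first exonic base after the
#'   intron), and `meta` (gene, intron length, intron start/end relative to
#'   the anchor).
#' @export
metagene_3ss <- function(alignments, genome, features, window = c(300L, 300L),
                         row_normalize = FALSE, total_mapped = NULL) {
  spliced <- features[features$tx_class == "mRNA" & features$n_exons > 1L, ,
                      drop = FALSE]
  if (nrow(spliced) == 0L) stop("no spliced mRNAs in the annotation")
  trk <- list()
  aln <- alignments[!alignments$multi, , drop = FALSE]
  if (is.null(total_mapped)) total_mapped <- nrow(aln)
  key <- function(chrom, strand) paste(chrom, strand)
  ilen <- integer(nrow(spliced))
  rows <- list(); meta <- list()
  for (i in seq_len(nrow(spliced))) {
    f <- spliced[i, ]
    introns <- feature_introns(f)
    tx_first <- if (f$strand == "+") 1L else nrow(introns)
    it <- introns[tx_first, , drop = FALSE]
    ilen[i] <- it[1L, 2L] - it[1L, 1L]
    k <- key(f$chrom, f$strand)
    if (is.null(trk[[k]])) {
      trk[[k]] <- pileup(aln, genome, f$chrom, kind = "hits", strand = f$strand,
                         total_mapped = total_mapped)
    }
    v <- trk[[k]]$values
    # anchor: first exonic base 3' of the intron, transcript orientation
    if (f$strand == "+") {
      anchor <- it[1L, 2L]
      pos <- seq.int(anchor - window[1L], anchor + window[2L] - 1L)
      vv <- rep(NA_real_, length(pos))
      ok <- pos >= 0L & pos < length(v)
      vv[ok] <- v[pos[ok] + 1L]
    } else {
      anchor <- it[1L, 1L] - 1L # last intronic base is anchor-1 in tx space
      pos <- seq.int(anchor + window[1L], anchor - window[2L] + 1L)
      vv <- rep(NA_real_, length(pos))
      ok <- pos >= 0L & pos < length(v)
      vv[ok] <- v[pos[ok] + 1L]
    }
    rows[[f$id]] <- vv
    meta[[f$id]] <- data.frame(gene = f$id, intron_length = ilen[i],
                               intron_rel_start = -ilen[i], intron_rel_end = 0L,
                               stringsAsFactors = FALSE)
  }
  ord <- order(-ilen, spliced$id)
  m <- do.call(rbind, rows[ord])
  colnames(m) <- seq.int(-window[1L], window[2L] - 1L)
  if (row_normalize) {
    mx <- apply(m, 1L, max, na.rm = TRUE)
    mx[!is.finite(mx) | mx == 0] <- 1
    m <- m / mx
  }
  list(matrix = m, meta = do.call(rbind, meta[ord]))
}

#' 5'-aligned tRNA family profiles
#'
#' Coverage matrix with one row per tRNA, ranked by precursor length
#' (including intron, descending), aligned at the mature 5' end and
#' retaining `flank` nt on both sides so 5'/3'-extended precursor reads are
#' visible.
#'
#' @inheritParams metagene_3ss
#' @param flank Flank width in nt.
#' @return List with `matrix` (rows = tRNAs, columns = positions relative to
#'   the mature 5' end, flank negative; positions beyond a tRNA's own
#'   precursor + flank are NA) and `meta` (id, precursor length, intron
#'   boundaries relative to the 5' end or NA).
#' @export
trna_profile <- function(alignments, genome, features, flank = 50L,
                         total_mapped = NULL) {
  trnas <- features[features$tx_class == "tRNA", , drop = FALSE]
  if (nrow(trnas) == 0L) {
    return(list(matrix = matrix(numeric(0), nrow = 0L), meta = NULL))
  }
  aln <- alignments[!alignments$multi, , drop = FALSE]
  if (is.null(total_mapped)) total_mapped <- nrow(aln)
  plen <- trnas$end - trnas$start
  width <- max(plen) + 2L * flank
  m <- matrix(NA_real_, nrow(trnas), width,
              dimnames = list(trnas$id, seq_len(width) - flank - 1L))
  meta <- list()
  trk <- list()
  for (i in seq_len(nrow(trnas))) {
    f <- trnas[i, ]
    k <- paste(f$chrom, f$strand)
    if (is.null(trk[[k]])) {
      trk[[k]] <- pileup(aln, genome, f$chrom, kind = "hits", strand = f$strand,
                         total_mapped = total_mapped)
    }
    prof <- rna_profile(trk[[k]], f, flank = flank)
    m[i, seq_along(prof)] <- prof
    introns <- feature_introns(f)
    irel <- if (nrow(introns) > 0L) {
      gmap <- template_map(f, "precursor")
      ist <- if (f$strand == "+") introns[1L, 1L] else introns[nrow(introns), 2L] - 1L
      match(ist, gmap) - 1L
    } else NA_integer_
    meta[[f$id]] <- data.frame(id = f$id, precursor_length = plen[i],
                               intron_rel_start = irel,
                               intron_length = if (nrow(introns)) {
                                 sum(introns[, 2L] - introns[, 1L])
                               } else 0L,
                               stringsAsFactors = FALSE)
  }
  ord <- order(-plen, trnas$id)
  list(matrix = m[ord, , drop = FALSE], meta = do.call(rbind, meta[ord]))
}

#' Write a coverage track as bedGraph
#'
#' 0-based half-open bedGraph with a track header; zero-valued runs are
#' omitted.
#'
#' @param track A `crac_track`.
#' @param path Output path.
#' @param name Track name for the header.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path, name = NULL) {
  if (is.null(name)) {
    name <- paste(track$kind, track$filter, track$strand, sep = "_")
  }
  r <- rle(track$values)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values != 0
  lines <- sprintf("%s\t%d\t%d\t%.10g", track$chrom, starts[keep], ends[keep],
                   r$values[keep])
  writeLines(c(sprintf("track type=bedGraph name=\"%s\"", name), lines), path)
  invisible(path)
}

#' Read a bedGraph track back into values
#'
#' @param path bedGraph path.
#' @param genome A `crac_genome`.
#' @param chrom Chromosome to extract.
#' @return Numeric vector over the chromosome.
#' @export
read_bedgraph <- function(path, genome, chrom) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  vals <- numeric(genome$lengths[[chrom]])
  gr <- gr[as.character(GenomicRanges::seqnames(gr)) == chrom]
  if (length(gr)) {
    for (i in seq_along(gr)) {
      vals[GenomicRanges::start(gr)[i]:GenomicRanges::end(gr)[i]] <-
        S4Vectors::mcols(gr)$score[i]
    }
  }
  vals
}
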