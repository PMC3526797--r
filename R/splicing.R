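#' Count junction-spanning reads
#'
#' A read counts toward a junction when its alignment covers the boundary
#' with at least `min_overhang` aligned nt on each side.  Exon-exon (EE)
#' counts require a junction-library (spliced) alignment; intron-exon
#' counts (IE5 at the 5' splice site, IE3 at the 3' splice site) require a
#' contiguous genomic M segment across the boundary.  Intron-mapped counts
#' include any read with at least one aligned base inside an mRNA intron
#' (excised-intron reads are indistinguishable from pre-mRNA reads); total
#' mRNA counts come from the attribution table.
#'
#' @param alignments A `crac_alignments` table in genomic coordinates (with
#'   junction metadata from [lift_junction_alignments()]).
#' @param junctions A `crac_junctions` table.
#' @param features A `crac_features` table.
#' @param attributions Attribution table from [assign_features()].
#' @param min_overhang Minimum aligned nt on each side of the boundary.
#' @return List with `per_gene` (data.frame: feature, EE, IE5, IE3,
#'   intron_reads, mRNA_reads) and `totals` (named numeric vector including
#'   the `IE_EE` and `introns_total_mRNA` ratios).
#' @export
count_junctions <- function(alignments, junctions, features, attributions,
                            min_overhang = 1L) {
  stopifnot(min_overhang >= 1L)
  aln <- alignments[!alignments$multi, , drop = FALSE]
  genes <- unique(junctions$feature)
  per <- data.frame(feature = genes, EE = 0, IE5 = 0, IE3 = 0,
                    intron_reads = 0, mRNA_reads = 0, stringsAsFactors = FALSE)

  # EE: junction-library alignments covering the splice with enough overhang
  jal <- which(aln$origin == "junction")
  for (i in jal) {
    feat <- aln$junc_feature[i]
    fu <- aln$junc_flank_up[i]
    # entry-space aligned span: M + D lengths (lifting adds only N ops)
    o <- cigar_ops(aln$cigar[i])[[1L]]
    espan <- sum(o$len[o$op %in% c("M", "D")])
    s <- aln$junc_off[i]
    if (s <= fu - min_overhang && s + espan >= fu + min_overhang) {
      per$EE[per$feature == feat] <- per$EE[per$feature == feat] + 1
    }
  }

  # IE: genomic alignments with an M segment containing the boundary window
  gal <- aln[aln$origin == "genome", , drop = FALSE]
  if (nrow(gal) > 0L) {
    seg <- aln_m_segments(gal)
    sgr <- GenomicRanges::GRanges(gal$chrom[seg$row],
                                  IRanges::IRanges(seg$start + 1L, seg$end),
                                  strand = gal$strand[seg$row])
    ie <- junctions[junctions$kind %in% c("IE5", "IE3"), , drop = FALSE]
    if (nrow(ie) > 0L) {
      wgr <- GenomicRanges::GRanges(ie$chrom,
                                    IRanges::IRanges(ie$coord - min_overhang + 1L,
                                                     ie$coord + min_overhang),
                                    strand = ie$strand)
      ov <- GenomicRanges::findOverlaps(wgr, sgr, type = "within")
      if (length(ov) > 0L) {
        qh <- S4Vectors::queryHits(ov)
        # one count per read per boundary
        key <- paste(qh, seg$row[S4Vectors::subjectHits(ov)])
        qh <- qh[!duplicated(key)]
        cnt <- table(qh)
        for (k in seq_along(cnt)) {
          j <- as.integer(names(cnt)[k])
          col <- ie$kind[j]
          per[per$feature == ie$feature[j], col] <-
            per[per$feature == ie$feature[j], col] + as.numeric(cnt[k])
        }
      }
    }

    # intron-mapped reads (>= 1 aligned base in an intron of a spliced gene)
    spliced <- features[features$id %in% genes, , drop = FALSE]
    irows <- list()
    for (i in seq_len(nrow(spliced))) {
      introns <- feature_introns(spliced[i, ])
      if (nrow(introns) == 0L) next
      irows[[length(irows) + 1L]] <- data.frame(
        feature = spliced$id[i], chrom = spliced$chrom[i],
        strand = spliced$strand[i],
        start = introns[, 1L], end = introns[, 2L], stringsAsFactors = FALSE)
    }
    if (length(irows)) {
      idf <- do.call(rbind, irows)
      igr <- GenomicRanges::GRanges(idf$chrom,
                                    IRanges::IRanges(idf$start + 1L, idf$end),
                                    strand = idf$strand)
      ov <- GenomicRanges::findOverlaps(igr, sgr)
      if (length(ov) > 0L) {
        key <- paste(S4Vectors::queryHits(ov), seg$row[S4Vectors::subjectHits(ov)])
        first <- !duplicated(key)
        qh <- S4Vectors::queryHits(ov)[first]
        cnt <- table(idf$feature[qh])
        per$intron_reads[match(names(cnt), per$feature)] <- as.numeric(cnt)
      }
    }
  }

  mr <- attributions[attributions$tx_class == "mRNA", , drop = FALSE]
  if (nrow(mr) > 0L) {
    cnt <- table(mr$feature)
    hit <- intersect(names(cnt), per$feature)
    per$mRNA_reads[match(hit, per$feature)] <- as.numeric(cnt[hit])
  }
  total_mRNA <- sum(table(mr$feature))
  totals <- c(EE = sum(per$EE), IE5 = sum(per$IE5), IE3 = sum(per$IE3),
              IE = sum(per$IE5) + sum(per$IE3),
              intron_reads = sum(per$intron_reads),
              total_mRNA_reads = as.numeric(total_mRNA))
  totals <- c(totals,
              IE_EE = if (totals[["EE"]] > 0) totals[["IE"]] / totals[["EE"]] else NA_real_,
              introns_total_mRNA = if (total_mRNA > 0) {
                totals[["intron_reads"]] / total_mRNA
              } else NA_real_)
  list(per_gene = per, totals = totals)
}

#' Ratio with standard error across replicates
#'
#' The ratio is computed per replicate (sum of numerators over sum of
#' denominators), then averaged; the SE is the sample SD over sqrt(r).  With
#' a single replicate the SE comes from a seeded bootstrap over genes (1,000
#' resamples by default), requiring per-gene numerator/denominator counts.
#'
#' @param num,den Numeric vectors of per-replicate totals.
#' @param boot_units Optional data.frame with per-gene columns `num`, `den`
#'   for the single-replicate bootstrap.
#' @param n_boot Number of bootstrap resamples.
#' @param seed Bootstrap RNG seed.
#' @return List with `ratio`, `se`, `ratios` (per replicate) and `excluded`
#'   (indices of replicates with zero denominator, dropped with a warning).
#' @export
ratio_with_se <- function(num, den, boot_units = NULL, n_boot = 1000L,
                          seed = 1L) {
  stopifnot(length(num) == length(den), length(num) >= 1L)
  bad <- which(den == 0)
  if (length(bad)) {
    warning("excluding replicate(s) with zero denominator: ",
            paste(bad, collapse = ", "))
    num <- num[-bad]; den <- den[-bad]
  }
  if (!length(num)) stop("no replicate with non-zero denominator")
  ratios <- num / den
  r <- length(ratios)
  if (r > 1L) {
    se <- stats::sd(ratios) / sqrt(r)
  } else if (!is.null(boot_units)) {
    set.seed(seed)
    n <- nrow(boot_units)
    bs <- vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      d <- sum(boot_units$den[idx])
      if (d == 0) NA_real_ else sum(boot_units$num[idx]) / d
    }, numeric(1))
    se <- stats::sd(bs, na.rm = TRUE)
  } else {
    se <- NA_real_
  }
  list(ratio = mean(ratios), se = se, ratios = ratios, excluded = bad)
}

#' Splice-site window preference (3'SS / 5'SS)
#'
#' Ratio of summed hit density in windows around 3' splice sites to windows
#' around 5' splice sites, over all introns of spliced genes, from
#' strand-matched coverage.
#'
#' @param alignments A `crac_alignments` table in genomic coordinates.
#' @param genome A `crac_genome`.
#' @param junctions A `crac_junctions` table (provides the SS coordinates).
#' @param window Half-width of the window in nt around each splice site.
#' @param total_mapped Library size for hpm weights.
#' @return List with `ratio`, `ss3` and `ss5` (summed hpm).
#' @export
ss_preference <- function(alignments, genome, junctions, window = 10L,
                          total_mapped = NULL) {
  ie <- junctions[junctions$kind %in% c("IE5", "IE3"), , drop = FALSE]
  if (nrow(ie) == 0L) stop("no spliced genes in the junction library")
  aln <- alignments[!alignments$multi, , drop = FALSE]
  if (is.null(total_mapped)) total_mapped <- nrow(aln)
  sums <- c(IE5 = 0, IE3 = 0)
  trk <- list()
  for (i in seq_len(nrow(ie))) {
    k <- paste(ie$chrom[i], ie$strand[i])
    if (is.null(trk[[k]])) {
      trk[[k]] <- pileup(aln, genome, ie$chrom[i], kind = "hits",
                         strand = ie$strand[i], total_mapped = total_mapped)
    }
    v <- trk[[k]]$values
    lo <- max(ie$coord[i] - window, 0L)
    hi <- min(ie$coord[i] + window, length(v))
    sums[ie$kind[i]] <- sums[ie$kind[i]] + sum(v[(lo + 1L):hi])
  }
  list(ratio = if (sums[["IE5"]] > 0) sums[["IE3"]] / sums[["IE5"]] else NA_real_,
       ss3 = unname(sums["IE3"]), ss5 = unname(sums["IE5"]))
}
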