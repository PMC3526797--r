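#' Attribute alignments to annotated features
#'
#' Every counted alignment (mapped, non-multi) receives exactly one
#' attribution.  Among same-strand features whose flank-extended span
#' overlaps the alignment, the highest-priority transcript class wins; ties
#' within a class are broken by the greatest overlap with the feature span,
#' then by lexicographic feature id.  Alignments overlapping nothing are
#' `intergenic`.  Reads within `flank` nt of a feature end attribute to the
#' feature with region `5'-flank`/`3'-flank`, capturing 5'/3'-extended
#' precursor reads.
#'
#' @param alignments A `crac_alignments` table in genomic coordinates.
#' @param features A `crac_features` table.
#' @param flank Flank capture width in nt (on both ends).
#' @param priority Ordered class vector, highest priority first.
#' @return Data.frame with one row per counted alignment: `read_id`,
#'   `feature`, `tx_class`, `polymerase`, `region` (one of exon, intron,
#'   5'-flank, 3'-flank, junction-EE, intergenic) and `count`.
#' @export
assign_features <- function(alignments, features, flank = 50L,
                            priority = crac_classes()) {
  aln <- alignments[!alignments$multi, , drop = FALSE]
  n <- nrow(aln)
  if (n == 0L) {
    return(data.frame(read_id = character(0), feature = character(0),
                      tx_class = character(0), polymerase = character(0),
                      region = character(0), count = integer(0),
                      stringsAsFactors = FALSE))
  }
  ends <- aln_end(aln)
  agr <- GenomicRanges::GRanges(aln$chrom,
                                IRanges::IRanges(aln$start + 1L, ends),
                                strand = aln$strand)
  fgr <- GenomicRanges::GRanges(
    features$chrom,
    IRanges::IRanges(pmax(features$start - flank, 0L) + 1L,
                     features$end + flank),
    strand = features$strand)
  ov <- GenomicRanges::findOverlaps(agr, fgr)
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  prio <- match(features$tx_class, priority)
  prio[is.na(prio)] <- length(priority) + 1L
  # overlap with the unextended feature span, for tie-breaking
  spanw <- pmax(0L, pmin(ends[qh], features$end[sh]) -
                     pmax(aln$start[qh], features$start[sh]))
  ord <- order(qh, prio[sh], -spanw, features$id[sh])
  qh <- qh[ord]; sh <- sh[ord]
  first <- !duplicated(qh)
  chosen <- rep(NA_integer_, n)
  chosen[qh[first]] <- sh[first]

  region <- rep("intergenic", n)
  feat <- rep("intergenic", n)
  txc <- rep("intergenic", n)
  pol <- rep(NA_character_, n)
  hitrows <- which(!is.na(chosen))
  for (i in hitrows) {
    f <- features[chosen[i], ]
    feat[i] <- f$id; txc[i] <- f$tx_class; pol[i] <- f$polymerase
    if (identical(aln$origin[i], "junction")) {
      region[i] <- "junction-EE"
      next
    }
    e <- f$exons[[1L]]
    in_exon <- any(aln$start[i] < e[, 2L] & ends[i] > e[, 1L])
    if (in_exon) {
      region[i] <- "exon"
    } else if (aln$start[i] < f$end && ends[i] > f$start) {
      region[i] <- "intron"
    } else {
      left <- ends[i] <= f$start
      region[i] <- if ((left && f$strand == "+") || (!left && f$strand == "-")) {
        "5'-flank"
      } else "3'-flank"
    }
  }
  data.frame(read_id = aln$read_id, feature = feat, tx_class = txc,
             polymerase = pol, region = region, count = aln$count,
             stringsAsFactors = FALSE)
}

#' Class distribution of attributed reads
#'
#' Percentage of counted reads per transcript class (including intergenic),
#' summing to 100.  By default every unique read counts once; with
#' `weight = "count"` reads are weighted by their collapsed duplicate
#' multiplicity, which recovers sampling proportions free of the
#' short-feature duplicate-collapse bias.
#'
#' @param attributions Attribution table from [assign_features()].
#' @param weight `"unique"` (default) or `"count"`.
#' @return Named numeric vector of percentages.
#' @export
class_distribution <- function(attributions, weight = c("unique", "count")) {
  weight <- match.arg(weight)
  if (nrow(attributions) == 0L) stop("no counted alignments")
  w <- if (weight == "count") attributions$count else rep(1L, nrow(attributions))
  tab <- tapply(w, attributions$tx_class, sum)
  pct <- 100 * as.vector(tab) / sum(tab)
  stats::setNames(pct, names(tab))
}

#' Polymerase partition of attributed reads
#'
#' Fraction of feature-attributed reads per transcribing polymerase
#' (Pol I / II / III), summing to 1.  Intergenic reads are excluded.
#'
#' @param attributions Attribution table.
#' @param weight `"unique"` (default) or `"count"` (duplicate multiplicity).
#' @return Named numeric vector over PolI, PolII, PolIII.
#' @export
polymerase_partition <- function(attributions, weight = c("unique", "count")) {
  weight <- match.arg(weight)
  sel <- !is.na(attributions$polymerase)
  if (!any(sel)) stop("no feature-attributed alignments")
  w <- if (weight == "count") attributions$count[sel] else rep(1L, sum(sel))
  tab <- tapply(w, factor(attributions$polymerase[sel],
                          levels = c("PolI", "PolII", "PolIII")), sum)
  tab[is.na(tab)] <- 0
  fr <- as.vector(tab) / sum(tab)
  stats::setNames(fr, names(tab))
}

#' A-tail frequency table
#'
#' Fraction of A-tailed reads overall and per polymerase class, mirroring
#' dataset-level oligo(A) summaries.
#'
#' @param attributions Attribution table.
#' @param tails Tail-call table from [call_tails()].
#' @param weight `"unique"` (default) or `"count"` (duplicate multiplicity).
#' @return Data.frame with rows total/PolI/PolII/PolIII and columns
#'   `n_reads`, `n_a_tailed`, `fraction` (NA for empty strata).
#' @export
atail_frequency_table <- function(attributions, tails,
                                  weight = c("unique", "count")) {
  weight <- match.arg(weight)
  m <- match(attributions$read_id, tails$read_id)
  if (anyNA(m)) stop("missing tail call for some attributed reads")
  at <- tails$a_tailed[m]
  w <- if (weight == "count") attributions$count else
    rep(1L, nrow(attributions))
  strata <- list(total = rep(TRUE, nrow(attributions)),
                 PolI = attributions$polymerase %in% "PolI",
                 PolII = attributions$polymerase %in% "PolII",
                 PolIII = attributions$polymerase %in% "PolIII")
  do.call(rbind, lapply(names(strata), function(s) {
    sel <- strata[[s]]
    n <- sum(w[sel]); k <- sum(w[at & sel])
    data.frame(stratum = s, n_reads = n, n_a_tailed = k,
               fraction = if (n > 0L) k / n else NA_real_,
               stringsAsFactors = FALSE)
  }))
}

#' Per-RNA count matrix in hits per million
#'
#' Counts attributed reads per feature (plus an `intergenic` row) for each
#' experiment and normalizes every column to hits per million mapped reads,
#' so each column sums to 1e6 exactly.
#'
#' @param attribution_list Named list of attribution tables, one per
#'   experiment.
#' @param features A `crac_features` table (defines the row universe).
#' @return Numeric matrix (features + intergenic) x experiments, in hpm.
#' @export
per_rna_counts <- function(attribution_list, features) {
  stopifnot(length(attribution_list) >= 1L)
  rows <- c(features$id, "intergenic")
  m <- sapply(attribution_list, function(at) {
    cnt <- table(factor(at$feature, levels = rows))
    tot <- sum(cnt)
    if (tot == 0L) rep(0, length(rows)) else 1e6 * as.vector(cnt) / tot
  })
  m <- matrix(m, nrow = length(rows),
              dimnames = list(rows, names(attribution_list)))
  m
}

#' log10(1 + x) display transform for hpm matrices
#'
#' @param m Numeric matrix in hpm.
#' @return Transformed matrix.
#' @export
hpm_log10 <- function(m) log10(1 + m)
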