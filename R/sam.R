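#' Write alignments as SAM
#'
#' Alignments must be in genomic coordinates (lift junction alignments
#' first).  Minus-strand records store the reverse-complemented read
#' sequence, as SAM requires; collapsed duplicate counts are stored in the
#' `XC` tag and the number of best loci in `NH`.
#'
#' @param alignments A `crac_alignments` table in genomic coordinates.
#' @param genome A `crac_genome` (for `@SQ` headers).
#' @param path Output path.
#' @param reads Optional reads table (`id`, `seq`) to fill the SEQ column;
#'   `*` is written when absent.
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, genome, path, reads = NULL) {
  if (any(alignments$origin == "junction" &
          !alignments$chrom %in% names(genome$seq))) {
    stop("junction alignments must be lifted to genomic coordinates before SAM export")
  }
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(genome$seq), genome$lengths))
  seqs <- rep("*", nrow(alignments))
  if (!is.null(reads)) {
    m <- match(alignments$read_id, reads$id)
    seqs <- reads$seq[m]
    neg <- alignments$strand == "-" & !is.na(seqs)
    seqs[neg] <- revcomp(seqs[neg])
    seqs[is.na(seqs)] <- "*"
  }
  flag <- ifelse(alignments$strand == "-", 16L, 0L)
  rec <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*\tNH:i:%d\tXC:i:%d",
                 alignments$read_id, flag, alignments$chrom,
                 alignments$start + 1L,
                 ifelse(alignments$multi, 0L, 255L),
                 alignments$cigar, seqs,
                 ifelse(alignments$multi, 2L, 1L), alignments$count)
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' Read a SAM file into an alignment table
#'
#' Accepts CIGAR ops M, I, D, N, S; `=`/`X` are normalized to M; hard clips
#' and padding are rejected with an explanatory error.  Coordinates are
#' converted to the internal 0-based convention, minus-strand sequences back
#' to read orientation, and the 3' soft-clipped read sequence is extracted.
#'
#' @param path SAM file path.
#' @return A `crac_alignments` table.
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (!length(lines)) {
    out <- data.frame(read_id = character(0), chrom = character(0),
                      strand = character(0), start = integer(0),
                      cigar = character(0), score = integer(0),
                      count = integer(0), multi = logical(0),
                      soft3 = character(0), origin = character(0),
                      stringsAsFactors = FALSE)
    class(out) <- c("crac_alignments", "data.frame")
    return(out)
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  get <- function(i) vapply(f, `[[`, character(1), i)
  flag <- as.integer(get(2))
  keep <- bitwAnd(flag, 4L) == 0L
  f <- f[keep]; flag <- flag[keep]
  get <- function(i) vapply(f, `[[`, character(1), i)
  cigar <- get(6)
  if (any(grepl("[HP]", cigar))) {
    stop("hard-clipped or padded CIGAR records are not supported")
  }
  cigar <- gsub("([0-9]+)[=X]", "\\1M", cigar)
  if (any(grepl("[^0-9MIDNS]", cigar))) {
    stop("unsupported CIGAR operation in: ",
         cigar[grepl("[^0-9MIDNS]", cigar)][1])
  }
  strand <- ifelse(bitwAnd(flag, 16L) != 0L, "-", "+")
  seqs <- get(10)
  neg <- strand == "-" & seqs != "*"
  seqs[neg] <- revcomp(seqs[neg])
  tag <- function(nm) {
    vapply(f, function(x) {
      hit <- grep(paste0("^", nm, ":i:"), x, value = TRUE)
      if (length(hit)) as.integer(sub(".*:", "", hit[1])) else NA_integer_
    }, integer(1))
  }
  nh <- tag("NH"); xc <- tag("XC")
  soft3 <- rep("", length(f))
  for (i in seq_along(f)) {
    if (seqs[i] == "*") next
    o <- cigar_ops(cigar[i])[[1L]]
    # read 3' clip: terminal S at reference right on +, left on -
    si <- if (strand[i] == "+") nrow(o) else 1L
    if (o$op[si] == "S") {
      sl <- o$len[si]
      soft3[i] <- substr(seqs[i], nchar(seqs[i]) - sl + 1L, nchar(seqs[i]))
    }
  }
  out <- data.frame(
    read_id = get(1), chrom = get(3), strand = strand,
    start = as.integer(get(4)) - 1L, cigar = cigar,
    score = NA_integer_,
    count = ifelse(is.na(xc), 1L, xc),
    multi = !is.na(nh) & nh > 1L,
    soft3 = soft3, origin = "genome", stringsAsFactors = FALSE)
  class(out) <- c("crac_alignments", "data.frame")
  out
}
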