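#' Load a reference genome from FASTA
#'
#' Reads a (multi-)FASTA file into an in-memory genome object.  Sequences are
#' uppercased and any character outside the ACGTN alphabet is replaced by N.
#'
#' @param path Path to a FASTA file.
#' @return An object of class `crac_genome`: a list with elements `seq`
#'   (named character vector of chromosome sequences) and `lengths`
#'   (named integer vector of chromosome lengths in nt).
#' @export
load_genome <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("empty FASTA file: ", path)
  nm <- sub("\\s.*$", "", names(ss))
  dup <- nm[duplicated(nm)]
  if (length(dup)) {
    stop("duplicate FASTA record name(s): ", paste(unique(dup), collapse = ", "))
  }
  seqs <- toupper(as.character(ss))
  seqs <- gsub("[^ACGTN]", "N", seqs)
  names(seqs) <- nm
  new_genome(seqs)
}

#' Construct a genome object from named sequences
#'
#' @param seqs Named character vector of chromosome sequences (ACGTN).
#' @return A `crac_genome` object.
#' @export
new_genome <- function(seqs) {
  stopifnot(is.character(seqs), !is.null(names(seqs)), !anyDuplicated(names(seqs)))
  if (any(grepl("[^ACGTN]", seqs))) stop("genome alphabet restricted to ACGTN")
  structure(
    list(seq = seqs, lengths = stats::setNames(nchar(seqs), names(seqs))),
    class = "crac_genome"
  )
}

#' Write a genome to FASTA
#'
#' @param genome A `crac_genome`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(genome$seq)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' @export
print.crac_genome <- function(x, ...) {
  cat("crac_genome:", length(x$seq), "sequence(s),",
      sum(as.numeric(x$lengths)), "nt total\n")
  invisible(x)
}

#' Extract a genomic subsequence (0-based half-open)
#'
#' @param genome A `crac_genome`.
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open interval.
#' @return Character scalar.
#' @export
genome_seq <- function(genome, chrom, start, end) {
  len <- unname(genome$lengths[chrom])
  if (is.na(len)) stop("unknown chromosome: ", chrom)
  if (start < 0 || end > len || start > end) {
    stop(sprintf("interval [%d,%d) outside %s (length %d)", start, end, chrom, len))
  }
  substr(genome$seq[[chrom]], start + 1L, end)
}

#' Reverse-complement DNA strings
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
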