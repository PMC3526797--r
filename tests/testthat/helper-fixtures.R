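# Small deterministic fixtures shared across tests.

# A 60-nt two-chromosome genome with known sequence content.
tiny_genome <- function() {
  new_genome(c(
    chrA = "ACGTACGTACGGGTCCCATGTTTGACCCGGGTTTACGTACGAAACCCGGGTTTAAACCCG",
    chrB = "TTTTGGGGCCCCAAAATTTTGGGGCCCCAAAA"
  ))
}

# One spliced plus-strand mRNA, one minus-strand tRNA, one snoRNA inside the
# mRNA intron -- enough structure for priority and junction logic.
tiny_features <- function() {
  new_features(
    id = c("geneA", "trnB", "snoC"),
    chrom = c("chrA", "chrB", "chrA"),
    strand = c("+", "-", "+"),
    exons = list(rbind(c(0L, 15L), c(35L, 55L)),
                 rbind(c(4L, 28L)),
                 rbind(c(18L, 30L))),
    tx_class = c("mRNA", "tRNA", "snoRNA")
  )
}

# Constructor for alignment tables in tests.
make_aln <- function(read_id, chrom, strand, start, cigar, count = 1L,
                     soft3 = "", origin = "genome", multi = FALSE) {
  out <- data.frame(read_id = read_id, chrom = chrom, strand = strand,
                    start = as.integer(start), cigar = cigar,
                    score = NA_integer_, count = as.integer(count),
                    multi = multi, soft3 = soft3, origin = origin,
                    stringsAsFactors = FALSE)
  class(out) <- c("crac_alignments", "data.frame")
  out
}

# Standard small simulation shared by several module tests.
std_sim <- function(n_reads = 4000L, seed = 5L, ...) {
  fg <- forge_genome(seed = 7L)
  cfg <- sim_config(n_reads = n_reads, seed = seed, ...)
  sim <- simulate_reads(fg$genome, fg$features, cfg)
  list(genome = fg$genome, features = fg$features, cfg = cfg,
       reads = sim$reads, manifest = sim$manifest)
}
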