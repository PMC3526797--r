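# Forge the synthetic study genome and annotation, simulate the five
# exosome-like conditions in duplicate, and record read accounting.
# The genome emulates a compressed yeast transcriptome: a 35S rRNA unit,
# 5S rRNA, spliced and intronless mRNAs (bimodal intron lengths), intron-
# containing tRNAs, sn/snoRNAs (including a Pol III U6), CUTs and SUTs.

source("analysis/00_config.R")

study <- load_study()
write_genome(study$genome, file.path(RESULTS_DIR, "study_genome.fa"))
write_annotation(study$features, file.path(RESULTS_DIR, "study_annotation.gff3"))
write_junction_fasta(study$junctions, file.path(RESULTS_DIR, "study_junctions.fa"))

acc <- do.call(rbind, lapply(names(study$experiments), function(l) {
  e <- study$experiments[[l]]
  data.frame(experiment = l, condition = e$condition,
             simulated = READS_PER_REP,
             unique_mapped = nrow(e$alignments),
             multi = sum(e$alignments$multi),
             a_tailed = sum(e$tails$a_tailed))
}))
write_tsv(acc, "read_accounting.tsv")

message(sprintf("genome: %d nt, %d features (%d spliced)",
                study$genome$lengths[[1]], nrow(study$features),
                sum(study$features$n_exons > 1)))
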