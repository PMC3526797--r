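# Coverage profiling: single-RNA profiles for structured RNAs, the 35S
# pre-rRNA track, the 3'SS-anchored pre-mRNA metagene (rows ordered by
# intron length) and 5'-aligned tRNA profiles with precursor flanks.

source("analysis/00_config.R")

study <- load_study()
e1 <- study$experiments[["nuclear_exo_rep1"]]  # structured-RNA-biased dataset

# 35S pre-rRNA coverage in transcript orientation
r35 <- study$features[study$features$tx_class == "rRNA_35S", ]
trk <- pileup(e1$alignments, study$genome, r35$chrom, kind = "hits",
              strand = r35$strand)
prof <- rna_profile(trk, r35, flank = 100L)
write_tsv(data.frame(position = as.integer(names(prof)), hpm = prof),
          "profile_rRNA_35S.tsv")
message(sprintf("35S track: peak %.0f hpm at position %s",
                max(prof, na.rm = TRUE),
                names(prof)[which.max(prof)]))

# example small structured RNAs (5S, a snoRNA, U6)
for (id in c(study$features$id[study$features$tx_class == "rRNA_5S"][1],
             study$features$id[study$features$tx_class == "snoRNA"][1],
             "snR-U6")) {
  fi <- study$features[study$features$id == id, ]
  t2 <- pileup(e1$alignments, study$genome, fi$chrom, kind = "hits",
               strand = fi$strand)
  p <- rna_profile(t2, fi, flank = 50L)
  write_tsv(data.frame(position = as.integer(names(p)), hpm = p),
            sprintf("profile_%s.tsv", gsub("[^A-Za-z0-9]", "_", id)))
}

# pre-mRNA metagene anchored at the 3' splice site
mg <- metagene_3ss(e1$alignments, study$genome, study$features,
                   window = c(300L, 300L))
write_tsv(data.frame(gene = rownames(mg$matrix), mg$matrix,
                     check.names = FALSE), "metagene_3ss.tsv")
write_tsv(mg$meta, "metagene_3ss_meta.tsv")
message(sprintf("metagene: %d spliced genes, intron lengths %d-%d nt",
                nrow(mg$matrix), min(mg$meta$intron_length),
                max(mg$meta$intron_length)))

# tRNAs ranked by precursor length, aligned at the mature 5' end
tp <- trna_profile(e1$alignments, study$genome, study$features, flank = 50L)
write_tsv(data.frame(id = rownames(tp$matrix), tp$matrix,
                     check.names = FALSE), "trna_profiles.tsv")
write_tsv(tp$meta, "trna_profiles_meta.tsv")
flank_mass <- sum(tp$matrix[, as.integer(colnames(tp$matrix)) < 0],
                  na.rm = TRUE)
message(sprintf("tRNA profiles: %d tRNAs; 5'-leader flank mass %.0f hpm",
                nrow(tp$matrix), flank_mass))
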