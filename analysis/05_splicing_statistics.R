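# Pre-mRNA vs mRNA statistics per condition: IE/EE junction ratio,
# introns/total-mRNA and the 3'SS/5'SS window preference, each with a
# standard error across the two replicates.  Overhang sensitivity is
# reported over {1, 3, 5} aligned nt.

source("analysis/00_config.R")

study <- load_study()
conds <- unique(vapply(study$experiments, `[[`, character(1), "condition"))

rows <- list(); sens <- list()
for (cn in conds) {
  labs <- names(study$experiments)[vapply(study$experiments, `[[`,
                                          character(1), "condition") == cn]
  per_rep <- lapply(labs, function(l) {
    e <- study$experiments[[l]]
    jc <- count_junctions(e$alignments, study$junctions, study$features,
                          e$attributions, min_overhang = 5L)
    ss <- ss_preference(e$alignments, study$genome, study$junctions)
    c(IE = jc$totals[["IE"]], EE = jc$totals[["EE"]],
      intron = jc$totals[["intron_reads"]],
      mrna = jc$totals[["total_mRNA_reads"]], ss3 = ss$ss3, ss5 = ss$ss5)
  })
  m <- do.call(rbind, per_rep)
  iee <- ratio_with_se(m[, "IE"], m[, "EE"])
  itm <- ratio_with_se(m[, "intron"], m[, "mrna"])
  ssp <- ratio_with_se(m[, "ss3"], m[, "ss5"])
  rows[[cn]] <- data.frame(condition = cn,
                           IE_EE = iee$ratio, IE_EE_se = iee$se,
                           introns_total_mRNA = itm$ratio,
                           introns_total_mRNA_se = itm$se,
                           ss3_ss5 = ssp$ratio, ss3_ss5_se = ssp$se)
  for (ov in c(1L, 3L, 5L)) {
    e <- study$experiments[[labs[1]]]
    jc <- count_junctions(e$alignments, study$junctions, study$features,
                          e$attributions, min_overhang = ov)
    sens[[paste(cn, ov)]] <- data.frame(condition = cn, min_overhang = ov,
                                        IE = jc$totals[["IE"]],
                                        EE = jc$totals[["EE"]],
                                        IE_EE = jc$totals[["IE_EE"]])
  }
}
tab <- do.call(rbind, rows)
write_tsv(tab, "splicing_ratios.tsv")
write_tsv(do.call(rbind, sens), "splicing_overhang_sensitivity.tsv")
message(paste(sprintf("%s: IE/EE=%.2f+-%.2f introns/mRNA=%.3f 3'SS/5'SS=%.2f",
                      tab$condition, tab$IE_EE, tab$IE_EE_se,
                      tab$introns_total_mRNA, tab$ss3_ss5), collapse = "\n"))
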