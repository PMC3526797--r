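# Transcript-class attribution: class distributions, polymerase partitions
# and the per-RNA hpm matrix that feeds the heat maps and clustering.

source("analysis/00_config.R")

study <- load_study()
attr_list <- lapply(study$experiments, `[[`, "attributions")

cls <- c(crac_classes(), "intergenic")
cd <- sapply(attr_list, function(at) {
  v <- class_distribution(at, weight = "count")
  out <- stats::setNames(numeric(length(cls)), cls)
  out[names(v)] <- v
  out
})
write_tsv(data.frame(class = rownames(cd), cd, check.names = FALSE),
          "class_distribution_pct.tsv")

pp <- sapply(attr_list, polymerase_partition, weight = "count")
write_tsv(data.frame(polymerase = rownames(pp), pp, check.names = FALSE),
          "polymerase_partition.tsv")
message("Pol III share by experiment: ",
        paste(sprintf("%s=%.1f%%", colnames(pp), 100 * pp["PolIII", ]),
              collapse = " "))

cm <- per_rna_counts(attr_list, study$features)
write_tsv(data.frame(feature = rownames(cm), cm, check.names = FALSE),
          "per_rna_hpm.tsv")
write_tsv(data.frame(feature = rownames(cm), hpm_log10(cm),
                     check.names = FALSE), "per_rna_hpm_log10.tsv")
stopifnot(all(abs(colSums(cm) - 1e6) < 1e-6))
message("hpm columns each sum to 1e6 across ", ncol(cm), " experiments")
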