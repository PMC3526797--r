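# Binding-profile clustering: complete linkage on correlation distance over
# log10(1+hpm) profiles, for experiments and for mRNAs, plus chi-square
# gene-set enrichment of the mRNA clusters.

source("analysis/00_config.R")

study <- load_study()
attr_list <- lapply(study$experiments, `[[`, "attributions")
cm <- per_rna_counts(attr_list, study$features)

# experiments axis: replicates should pair up
d_exp <- correlation_distance(t(cm))
hc_exp <- complete_linkage(d_exp)
write_newick(hc_exp, file.path(RESULTS_DIR, "experiments.nwk"))
first_pairs <- hc_exp$merge[hc_exp$merge[, 1] < 0 & hc_exp$merge[, 2] < 0, ,
                            drop = FALSE]
pair_labels <- apply(first_pairs, 1, function(r) {
  paste(sort(hc_exp$labels[-r]), collapse = " + ")
})
message("leaf-pair merges: ", paste(pair_labels, collapse = "; "))

# mRNA axis with gene-set enrichment
mids <- study$features$id[study$features$tx_class == "mRNA"]
mm <- cm[mids, , drop = FALSE]
mm <- mm[apply(mm, 1, stats::sd) > 0, , drop = FALSE]
hc_m <- complete_linkage(correlation_distance(mm))
write_newick(hc_m, file.path(RESULTS_DIR, "mrnas.nwk"))
enr <- cut_and_enrich(hc_m, k = 3, gene_set_list(study$features))
write_tsv(enr, "mrna_cluster_enrichment.tsv")
top <- enr[order(enr$p), ][1, ]
message(sprintf("strongest enrichment: cluster %d x %s, p = %.3g (%s)",
                top$cluster, top$set, top$p, top$method))

cl <- stats::cutree(hc_m, k = 3)
write_tsv(data.frame(feature = names(cl), cluster = cl),
          "mrna_cluster_assignments.tsv")
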