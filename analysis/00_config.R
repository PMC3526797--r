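# Shared setup for the analysis scripts: forge the study genome, build the
# junction library, and process the five-condition / two-replicate synthetic
# CRAC study (simulate -> collapse -> trim -> align -> lift -> tails ->
# attribution).  Processed objects are cached under scratch/ so the numbered
# scripts can be re-run individually; delete scratch/ to rebuild.

library(cracseq)

STUDY_SEED <- 20120901L   # forge seed for the study genome
READS_PER_REP <- 20000L
RESULTS_DIR <- "results/analysis"
CACHE <- "scratch/condition_study.rds"

dir.create(RESULTS_DIR, showWarnings = FALSE, recursive = TRUE)
dir.create("scratch", showWarnings = FALSE)

load_study <- function() {
  if (file.exists(CACHE)) return(readRDS(CACHE))
  fg <- forge_genome(seed = STUDY_SEED)
  junc <- build_junction_library(fg$features, fg$genome, flank = 50L)
  presets <- crac_condition_presets()
  exps <- list()
  for (ci in seq_along(presets)) {
    for (r in 1:2) {
      lab <- sprintf("%s_rep%d", names(presets)[ci], r)
      cfg <- condition_config(fg$features, presets[[ci]],
                              n_reads = READS_PER_REP,
                              seed = 100L * ci + r)
      sim <- simulate_reads(fg$genome, fg$features, cfg)
      tr <- trim_adapter(collapse_duplicates(sim$reads), cfg$adapter)
      al <- lift_junction_alignments(align_reads(tr, fg$genome, junc),
                                     junc, fg$features)
      tc <- call_tails(al, fg$genome, adapter = cfg$adapter)
      exps[[lab]] <- list(
        condition = names(presets)[ci], replicate = r,
        alignments = tc$alignments, tails = tc$tails,
        attributions = assign_features(tc$alignments, fg$features),
        manifest = sim$manifest)
      message("processed ", lab, ": ", nrow(tc$alignments), " mapped reads")
    }
  }
  study <- list(genome = fg$genome, features = fg$features, junctions = junc,
                experiments = exps)
  saveRDS(study, CACHE)
  study
}

write_tsv <- function(x, file, row.names = FALSE) {
  utils::write.table(x, file.path(RESULTS_DIR, file), sep = "\t",
                     quote = FALSE, row.names = row.names)
  message("wrote ", file.path(RESULTS_DIR, file))
}
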