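#' Simulation presets for exosome-subunit-like conditions
#'
#' Named parameter sets emulating the qualitative binding signatures of
#' exosome datasets: a wild-type-like ribonuclease (low oligo(A) fraction,
#' ~5% Pol III), its endonuclease-dead twin, an exonuclease-dead mutant
#' (high oligo(A) fraction, ~40% Pol III, strong pre-mRNA binding), a
#' nuclear exonuclease enriched on small structured RNAs and introns, and a
#' TRAMP poly(A) polymerase (highest oligo(A) fraction, ~18% Pol III).  Each
#' preset lists `class_weights`, `a_tail_prob`, `pre_mature_ratio` and a
#' `condition_seed` used to derive condition-specific per-feature binding
#' preferences shared across replicates.
#'
#' @return Named list of preset parameter lists.
#' @export
crac_condition_presets <- function() {
  list(
    rnase_wt = list(
      class_weights = c(rRNA_35S = 0.35, mRNA = 0.32, snoRNA = 0.10,
                        CUT = 0.09, SUT = 0.06, snRNA = 0.03, tRNA = 0.03,
                        rRNA_5S = 0.01, scR1 = 0.005, other_polIII = 0.005),
      a_tail_prob = c(rRNA_35S = 0.006, mRNA = 0.006, snoRNA = 0.006,
                      CUT = 0.006, SUT = 0.006, snRNA = 0.006, tRNA = 0.10,
                      rRNA_5S = 0.10, scR1 = 0.10, other_polIII = 0.10),
      pre_mature_ratio = 0.30, condition_seed = 101L),
    rnase_endo = list(
      class_weights = c(rRNA_35S = 0.34, mRNA = 0.33, snoRNA = 0.10,
                        CUT = 0.09, SUT = 0.06, snRNA = 0.03, tRNA = 0.03,
                        rRNA_5S = 0.01, scR1 = 0.005, other_polIII = 0.005),
      a_tail_prob = c(rRNA_35S = 0.004, mRNA = 0.004, snoRNA = 0.004,
                      CUT = 0.004, SUT = 0.004, snRNA = 0.004, tRNA = 0.08,
                      rRNA_5S = 0.08, scR1 = 0.08, other_polIII = 0.08),
      pre_mature_ratio = 0.30, condition_seed = 102L),
    rnase_exo = list(
      class_weights = c(rRNA_35S = 0.10, mRNA = 0.15, snoRNA = 0.12,
                        CUT = 0.10, SUT = 0.08, snRNA = 0.05, tRNA = 0.20,
                        rRNA_5S = 0.08, scR1 = 0.06, other_polIII = 0.06),
      a_tail_prob = 0.195,
      pre_mature_ratio = 0.60, condition_seed = 103L),
    nuclear_exo = list(
      class_weights = c(rRNA_35S = 0.20, mRNA = 0.28, snoRNA = 0.18,
                        CUT = 0.08, SUT = 0.06, snRNA = 0.08, tRNA = 0.08,
                        rRNA_5S = 0.02, scR1 = 0.01, other_polIII = 0.01),
      a_tail_prob = 0.10,
      pre_mature_ratio = 0.61, condition_seed = 104L),
    polyA_pol = list(
      class_weights = c(rRNA_35S = 0.15, mRNA = 0.25, snoRNA = 0.15,
                        CUT = 0.12, SUT = 0.108, snRNA = 0.04, tRNA = 0.10,
                        rRNA_5S = 0.04, scR1 = 0.022, other_polIII = 0.02),
      a_tail_prob = 0.403,
      pre_mature_ratio = 0.40, condition_seed = 105L)
  )
}

#' Condition-specific per-feature binding weights
#'
#' Log-normal multipliers (sdlog 0.8) drawn from a condition seed, shared by
#' all replicates of a condition; they model per-RNA binding preference on
#' top of the class weights.
#'
#' @param features A `crac_features` table.
#' @param condition_seed Integer seed identifying the condition.
#' @param sdlog SD of the log-normal multiplier.
#' @return Named numeric vector of multipliers.
#' @export
condition_feature_weights <- function(features, condition_seed, sdlog = 0.8) {
  set.seed(condition_seed)
  stats::setNames(stats::rlnorm(nrow(features), 0, sdlog), features$id)
}

#' Build a simulation config for a preset condition
#'
#' @param features A `crac_features` table.
#' @param preset One element of [crac_condition_presets()].
#' @param n_reads Reads to simulate.
#' @param seed Read-sampling seed (vary across replicates).
#' @param ... Further overrides passed to [sim_config()].
#' @return A `sim_config`.
#' @export
condition_config <- function(features, preset, n_reads = 50000L, seed = 1L, ...) {
  args <- list(n_reads = n_reads, seed = seed,
               class_weights = preset$class_weights,
               a_tail_prob = preset$a_tail_prob,
               pre_mature_ratio = preset$pre_mature_ratio,
               feature_weights = condition_feature_weights(features,
                                                           preset$condition_seed),
               ...)
  do.call(sim_config, args)
}

pipeline_keys <- c("forge", "experiments", "flank_junction", "flank_attr",
                   "min_A", "tail_purity", "min_overhang", "priority",
                   "cluster_k", "seed_length", "adapter", "metagene_window",
                   "trna_flank")

#' Run the full synthetic CRAC analysis pipeline
#'
#' Orchestrates forge -> simulate -> collapse/trim -> align -> tail and
#' deletion calling -> attribution -> profiles -> splice statistics ->
#' clustering for a multi-experiment configuration, writing all tables under
#' one output directory together with a JSON run manifest (configuration and
#' output checksums).  Deterministic given the configured seeds.
#'
#' @param config Nested list.  Recognised keys: `forge` (arguments to
#'   [forge_genome()]), `experiments` (named list; each element has `preset`
#'   (a preset name or parameter list) and `seed`, plus optional `n_reads`),
#'   `flank_junction`, `flank_attr`, `min_A`, `tail_purity`, `min_overhang`,
#'   `priority`, `cluster_k`, `seed_length`, `metagene_window`, `trna_flank`.
#'   Unknown keys are an error before any computation.
#' @param outdir Output directory (created; must be empty or absent).
#' @return `outdir`, invisibly; side effect: files written.
#' @export
run_pipeline <- function(config, outdir) {
  unknown <- setdiff(names(config), pipeline_keys)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  if (is.null(config$experiments) || !length(config$experiments)) {
    stop("configuration must define at least one experiment")
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  emit <- function(obj, file, row.names = FALSE) {
    p <- file.path(outdir, file)
    utils::write.table(obj, p, sep = "\t", quote = FALSE, row.names = row.names)
    written <<- c(written, p)
    p
  }
  stage <- "forge"
  res <- tryCatch({
    forged <- do.call(forge_genome, config$forge %||% list())
    genome <- forged$genome; features <- forged$features
    p <- file.path(outdir, "genome.fa"); write_genome(genome, p)
    written <- c(written, p)
    p <- file.path(outdir, "annotation.gff3"); write_annotation(features, p)
    written <- c(written, p)

    stage <- "junctions"
    junc <- build_junction_library(features, genome,
                                   flank = config$flank_junction %||% 50L)
    p <- file.path(outdir, "junctions.fa"); write_junction_fasta(junc, p)
    written <- c(written, p)

    presets <- crac_condition_presets()
    attr_list <- list(); tail_tabs <- list(); counts_log <- list()
    aln_by_exp <- list(); tails_by_exp <- list()
    stage <- "experiments"
    for (label in names(config$experiments)) {
      ex <- config$experiments[[label]]
      preset <- if (is.character(ex$preset)) presets[[ex$preset]] else ex$preset
      if (is.null(preset)) stop("unknown preset for experiment ", label)
      cfg <- condition_config(features, preset,
                              n_reads = ex$n_reads %||% 50000L,
                              seed = ex$seed %||% 1L)
      sim <- simulate_reads(genome, features, cfg)
      uq <- collapse_duplicates(sim$reads)
      tr <- trim_adapter(uq, cfg$adapter)
      aln <- align_reads(tr, genome, junc,
                         seed_length = config$seed_length %||% 12L)
      aln <- lift_junction_alignments(aln, junc, features)
      tc <- call_tails(aln, genome, min_A = config$min_A %||% 2L,
                       purity = config$tail_purity %||% 1,
                       adapter = cfg$adapter)
      aln <- tc$alignments
      at <- assign_features(aln, features,
                            flank = config$flank_attr %||% 50L,
                            priority = config$priority %||% crac_classes())
      attr_list[[label]] <- at
      tail_tabs[[label]] <- atail_frequency_table(at, tc$tails)
      aln_by_exp[[label]] <- aln
      tails_by_exp[[label]] <- tc$tails
      counts_log[[label]] <- data.frame(
        experiment = label, simulated = nrow(sim$reads), unique = nrow(uq),
        trimmed_kept = nrow(tr), mapped = nrow(aln),
        multi = sum(aln$multi), counted = sum(!aln$multi),
        stringsAsFactors = FALSE)
      dels <- extract_deletions(aln)
      emit(tc$tails, sprintf("tails_%s.tsv", label))
      emit(dels, sprintf("deletions_%s.tsv", label))
      sam <- file.path(outdir, sprintf("alignments_%s.sam", label))
      write_sam(aln, genome, sam, reads = tr)
      written <- c(written, sam)
    }
    emit(do.call(rbind, counts_log), "read_accounting.tsv")

    stage <- "class_tables"
    cd <- sapply(attr_list, function(at) {
      v <- class_distribution(at)
      all <- c(crac_classes(), "intergenic")
      out <- stats::setNames(numeric(length(all)), all)
      out[names(v)] <- v
      out
    })
    emit(data.frame(class = rownames(cd), cd, check.names = FALSE),
         "class_distribution.tsv")
    pp <- sapply(attr_list, polymerase_partition)
    emit(data.frame(polymerase = rownames(pp), pp, check.names = FALSE),
         "polymerase_partition.tsv")
    at_tab <- do.call(rbind, lapply(names(tail_tabs), function(l) {
      cbind(experiment = l, tail_tabs[[l]])
    }))
    emit(at_tab, "atail_frequencies.tsv")

    stage <- "count_matrix"
    cm <- per_rna_counts(attr_list, features)
    emit(data.frame(feature = rownames(cm), cm, check.names = FALSE),
         "per_rna_hpm.tsv")

    stage <- "profiles"
    first <- names(config$experiments)[1L]
    aln1 <- aln_by_exp[[first]]
    for (kind in c("hits", "dels")) {
      for (filt in c("total", "a_tailed")) {
        for (str in c("+", "-")) {
          trkk <- pileup(aln1, genome, names(genome$seq)[1L], kind = kind,
                         filter = filt, tails = tails_by_exp[[first]],
                         strand = str)
          p <- file.path(outdir, sprintf("%s_%s_%s_%s.bedgraph", first, kind,
                                         filt, ifelse(str == "+", "plus", "minus")))
          write_bedgraph(trkk, p)
          written <- c(written, p)
        }
      }
    }
    mg <- metagene_3ss(aln1, genome, features,
                       window = config$metagene_window %||% c(300L, 300L))
    emit(data.frame(gene = rownames(mg$matrix), mg$matrix, check.names = FALSE),
         "metagene_3ss.tsv")
    emit(mg$meta, "metagene_3ss_meta.tsv")
    tp <- trna_profile(aln1, genome, features,
                       flank = config$trna_flank %||% 50L)
    if (nrow(tp$matrix) > 0L) {
      emit(data.frame(id = rownames(tp$matrix), tp$matrix, check.names = FALSE),
           "trna_profiles.tsv")
      emit(tp$meta, "trna_profiles_meta.tsv")
    }

    stage <- "splicing"
    jc_tot <- lapply(names(attr_list), function(l) {
      count_junctions(aln_by_exp[[l]], junc, features, attr_list[[l]],
                      min_overhang = config$min_overhang %||% 1L)
    })
    names(jc_tot) <- names(attr_list)
    sp <- do.call(rbind, lapply(names(jc_tot), function(l) {
      data.frame(experiment = l, t(jc_tot[[l]]$totals), check.names = FALSE)
    }))
    ssr <- vapply(names(attr_list), function(l) {
      ss_preference(aln_by_exp[[l]], genome, junc)$ratio
    }, numeric(1))
    sp$ss3_ss5 <- ssr
    emit(sp, "splicing_stats.tsv")

    stage <- "clustering"
    if (length(attr_list) >= 2L) {
      d_exp <- correlation_distance(t(cm))
      hc_exp <- complete_linkage(d_exp)
      p <- file.path(outdir, "experiments.nwk"); write_newick(hc_exp, p)
      written <- c(written, p)
      mids <- features$id[features$tx_class == "mRNA"]
      mm <- cm[mids, , drop = FALSE]
      keep <- apply(mm, 1L, stats::sd) > 0
      if (sum(keep) >= 3L) {
        d_m <- correlation_distance(mm[keep, , drop = FALSE])
        hc_m <- complete_linkage(d_m)
        p <- file.path(outdir, "mrnas.nwk"); write_newick(hc_m, p)
        written <- c(written, p)
        k <- config$cluster_k %||% 2L
        gs <- gene_set_list(features)
        if (length(gs) && k <= sum(keep)) {
          enr <- cut_and_enrich(hc_m, k, gs)
          emit(enr, "enrichment.tsv")
        }
      }
    }

    stage <- "manifest"
    sums <- tools::md5sum(sort(written))
    manifest <- list(config = config,
                     outputs = as.list(stats::setNames(unname(sums),
                                                       basename(names(sums)))))
    mp <- file.path(outdir, "run_manifest.json")
    jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    outdir
  }, error = function(e) {
    unlink(written)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(res)
}
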