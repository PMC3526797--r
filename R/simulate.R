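#' Forge a synthetic genome and annotation
#'
#' Generates a random-sequence genome with non-overlapping embedded features
#' emulating the composition of the budding-yeast transcriptome at desk
#' scale: intron-containing mRNAs with a bimodal intron-length mix (long
#' introns carry a `ribosomal_protein` gene-set label), intronless mRNAs,
#' intron-containing and intronless tRNAs, snoRNAs, snRNAs including a
#' Pol III-transcribed U6, a 35S rDNA unit (whose 5' portion stands in for
#' the 5'-ETS), 5S rRNA, scR1, CUTs and SUTs.
#'
#' @param counts Named integer vector of feature counts per kind.  Recognised
#'   names: `mRNA_spliced_long`, `mRNA_spliced_short`, `mRNA`, `tRNA`,
#'   `tRNA_spliced`, `snoRNA`, `snRNA`, `U6`, `CUT`, `SUT`, `rRNA_5S`,
#'   `rRNA_35S`, `scR1`, `other_polIII`.
#' @param seed Integer RNG seed; with a fixed seed the output is
#'   byte-identical across runs.
#' @param alphabet Bases used for the random genome (default ACGT).  A
#'   reduced alphabet (e.g. no A) gives a genome free of templated A runs,
#'   used to validate tail calling under unambiguous conditions.
#' @param strands Strands features may be placed on.
#' @param spacer Range (min, max) of intergenic spacer lengths in nt.
#' @param chrom_name Name of the single synthetic chromosome.
#' @return List with elements `genome` (a `crac_genome`) and `features`
#'   (a `crac_features` table).
#' @export
forge_genome <- function(counts = c(mRNA_spliced_long = 4, mRNA_spliced_short = 4,
                                    mRNA = 8, tRNA = 6, tRNA_spliced = 3,
                                    snoRNA = 4, snRNA = 2, U6 = 1, CUT = 4,
                                    SUT = 4, rRNA_5S = 1, rRNA_35S = 1,
                                    scR1 = 1, other_polIII = 1),
                         seed = 1L,
                         alphabet = c("A", "C", "G", "T"),
                         strands = c("+", "-"),
                         spacer = c(150L, 300L),
                         chrom_name = "chrS") {
  counts <- counts[counts > 0]
  if (length(counts) == 0L || sum(counts) == 0L) stop("zero total features requested")
  known <- c("mRNA_spliced_long", "mRNA_spliced_short", "mRNA", "tRNA",
             "tRNA_spliced", "snoRNA", "snRNA", "U6", "CUT", "SUT",
             "rRNA_5S", "rRNA_35S", "scR1", "other_polIII")
  if (any(!names(counts) %in% known)) {
    stop("unknown feature kind(s): ",
         paste(setdiff(names(counts), known), collapse = ", "))
  }
  set.seed(seed)
  rint <- function(lo, hi) sample.int(hi - lo + 1L, 1L) + lo - 1L

  specs <- list() # per feature: exon lengths / intron lengths / class / pol / sets
  add <- function(exlens, inlens, cls, pol = NA_character_, sets = "", idp) {
    specs[[length(specs) + 1L]] <<- list(ex = as.integer(exlens),
                                         intron = as.integer(inlens),
                                         cls = cls, pol = pol, sets = sets,
                                         idp = idp)
  }
  for (kind in names(counts)) {
    for (r in seq_len(counts[[kind]])) {
      switch(kind,
        mRNA_spliced_long = add(c(rint(120, 180), rint(500, 900)), rint(380, 420),
                                "mRNA", sets = "intron_containing,ribosomal_protein",
                                idp = "mRL"),
        mRNA_spliced_short = add(c(rint(120, 180), rint(400, 700)), rint(90, 110),
                                 "mRNA", sets = "intron_containing", idp = "mRS"),
        mRNA = add(rint(700, 1400), integer(0), "mRNA",
                   sets = if (r %% 2L == 0L) "ribosome_synthesis_factor" else "",
                   idp = "mRN"),
        tRNA = add(rint(72, 95), integer(0), "tRNA", idp = "tRN"),
        tRNA_spliced = add(c(rint(30, 40), rint(38, 55)), rint(14, 30), "tRNA",
                           idp = "tRS"),
        snoRNA = add(rint(90, 200), integer(0), "snoRNA", idp = "sno"),
        snRNA = add(rint(120, 300), integer(0), "snRNA", idp = "snR"),
        U6 = add(112L, integer(0), "snRNA", pol = "PolIII", idp = "U6"),
        CUT = add(rint(200, 400), integer(0), "CUT", idp = "CUT"),
        SUT = add(rint(200, 500), integer(0), "SUT", idp = "SUT"),
        rRNA_5S = add(121L, integer(0), "rRNA_5S", idp = "R5S"),
        rRNA_35S = add(2500L, integer(0), "rRNA_35S", idp = "R35"),
        scR1 = add(520L, integer(0), "scR1", idp = "scR"),
        other_polIII = add(rint(100, 160), integer(0), "other_polIII", idp = "oP3")
      )
    }
  }

  ids <- character(length(specs))
  tabs <- integer(0)
  for (i in seq_along(specs)) {
    p <- specs[[i]]$idp
    tabs[p] <- if (is.na(tabs[p])) 1L else tabs[p] + 1L
    ids[i] <- if (p == "U6") "snR-U6" else sprintf("%s-%03d", p, tabs[p])
  }

  exons <- vector("list", length(specs))
  strand <- character(length(specs))
  pos <- 0L
  for (i in seq_along(specs)) {
    pos <- pos + rint(spacer[1], spacer[2])
    sp <- specs[[i]]
    strand[i] <- if (length(strands) == 1L) strands else sample(strands, 1L)
    segs <- integer(0)
    e <- matrix(integer(0), ncol = 2L)
    at <- pos
    for (j in seq_along(sp$ex)) {
      e <- rbind(e, c(at, at + sp$ex[j]))
      at <- at + sp$ex[j]
      if (j <= length(sp$intron)) at <- at + sp$intron[j]
    }
    exons[[i]] <- e
    pos <- at
  }
  glen <- pos + rint(spacer[1], spacer[2])
  seqc <- paste(sample(alphabet, glen, replace = TRUE), collapse = "")
  genome <- new_genome(stats::setNames(seqc, chrom_name))

  feats <- new_features(
    id = ids, chrom = chrom_name, strand = strand, exons = exons,
    tx_class = vapply(specs, `[[`, character(1), "cls"),
    polymerase = vapply(specs, `[[`, character(1), "pol"),
    gene_sets = vapply(specs, `[[`, character(1), "sets")
  )
  list(genome = genome, features = feats)
}

#' Simulation configuration for CRAC-like reads
#'
#' Collects every knob of the read simulator.  Defaults describe a generic
#' CRAC library: short (20-50 nt) strand-specific reads, positional profiles
#' mixing a uniform background with a peak at the crosslink site,
#' reverse-transcriptase microdeletions at the crosslink site (1 nt with
#' probability 0.8, 2 nt with probability 0.2), class-dependent non-templated
#' oligo(A) tailing with geometric tail lengths of at least 2 nt, and a 3'
#' sequencing adapter appended when the insert is shorter than the read
#' cycle length.
#'
#' @param n_reads Number of reads to simulate.
#' @param read_length Integer (min, max) read length in nt.
#' @param class_weights Named relative sampling mass per transcript class.
#' @param feature_weights Optional named per-feature multipliers on top of
#'   the class weights (per-RNA binding preference).
#' @param peak_frac Fraction of reads drawn from the peaked positional
#'   component (the remainder is uniform over the template).
#' @param peak_width SD (nt) of the Gaussian positional peak centred so reads
#'   cover the crosslink site.
#' @param crosslink_sites Optional named list mapping feature id to precursor
#'   transcript coordinates of crosslink sites; by default one deterministic
#'   site per feature at 45% of the precursor length.
#' @param delete_prob Probability that a read covering a crosslink site
#'   acquires a microdeletion there (the simulator's delta).
#' @param del_len_probs Probabilities of deletion lengths 1 and 2 nt.
#' @param a_tail_prob Named per-class probability that a read receives a
#'   non-templated oligo(A) tail (the simulator's pi_A); a single unnamed
#'   value applies to all classes.
#' @param tail_geom_p Success probability of the geometric tail-length
#'   distribution; tail length = 2 + Geom(p).
#' @param seq_error Per-nt substitution error rate.
#' @param pre_mature_ratio Probability that a read from a spliced gene (or a
#'   gene with a precursor flank) derives from the unspliced precursor rather
#'   than the mature RNA.
#' @param precursor_flank Named per-class extension of the precursor template
#'   beyond the annotated span, in nt (default 15 nt for tRNAs, emulating
#'   pre-tRNA 5' leaders and 3' trailers); precursor-template reads may
#'   extend into this flanking sequence.
#' @param antisense_rate Probability of an antisense (strand-flipped) read;
#'   CRAC libraries are strand-specific, so the default is 0.
#' @param adapter 3' adapter sequence.
#' @param seed Integer RNG seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_reads = 50000L,
                       read_length = c(20L, 50L),
                       class_weights = c(rRNA_35S = 0.33, mRNA = 0.30,
                                         snoRNA = 0.10, CUT = 0.09, SUT = 0.06,
                                         snRNA = 0.03, tRNA = 0.03,
                                         rRNA_5S = 0.01, scR1 = 0.005,
                                         other_polIII = 0.005),
                       feature_weights = NULL,
                       peak_frac = 0.7,
                       peak_width = 10,
                       crosslink_sites = NULL,
                       delete_prob = 0.15,
                       del_len_probs = c(0.8, 0.2),
                       a_tail_prob = 0.05,
                       tail_geom_p = 0.5,
                       seq_error = 0.002,
                       pre_mature_ratio = 0.5,
                       precursor_flank = c(tRNA = 15L),
                       antisense_rate = 0,
                       adapter = "TCGTATGCCGTCTTCTGCTTG",
                       seed = 1L) {
  cfg <- list(n_reads = as.integer(n_reads), read_length = as.integer(read_length),
              class_weights = class_weights, feature_weights = feature_weights,
              peak_frac = peak_frac, peak_width = peak_width,
              crosslink_sites = crosslink_sites, delete_prob = delete_prob,
              del_len_probs = del_len_probs, a_tail_prob = a_tail_prob,
              tail_geom_p = tail_geom_p, seq_error = seq_error,
              pre_mature_ratio = pre_mature_ratio,
              precursor_flank = precursor_flank,
              antisense_rate = antisense_rate,
              adapter = adapter, seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_reads >= 0L,
            length(cfg$read_length) == 2L,
            cfg$read_length[1] >= 1L, cfg$read_length[2] >= cfg$read_length[1],
            all(cfg$class_weights >= 0), any(cfg$class_weights > 0),
            cfg$delete_prob >= 0, cfg$delete_prob <= 1,
            all(cfg$a_tail_prob >= 0), all(cfg$a_tail_prob <= 1),
            cfg$seq_error >= 0, cfg$seq_error <= 1,
            cfg$pre_mature_ratio >= 0, cfg$pre_mature_ratio <= 1,
            is.null(cfg$precursor_flank) || all(cfg$precursor_flank >= 0),
            cfg$peak_frac >= 0, cfg$peak_frac <= 1,
            cfg$tail_geom_p > 0, cfg$tail_geom_p <= 1,
            nchar(cfg$adapter) >= 1L)
  invisible(cfg)
}

class_tail_prob <- function(cfg, tx_class) {
  p <- cfg$a_tail_prob
  if (is.null(names(p))) rep_len(p[1], length(tx_class)) else {
    out <- unname(p[tx_class])
    out[is.na(out)] <- 0
    out
  }
}

#' Default crosslink sites for a feature table
#'
#' One deterministic site per feature at 45% of the precursor length, unless
#' overridden in the configuration.
#'
#' @param features A `crac_features` table.
#' @param cfg A `sim_config`.
#' @return Named list mapping feature id to precursor transcript coordinates.
#' @export
resolve_crosslink_sites <- function(features, cfg) {
  sites <- stats::setNames(
    lapply(seq_len(nrow(features)), function(i) {
      as.integer(floor(0.45 * (features$end[i] - features$start[i])))
    }), features$id)
  if (!is.null(cfg$crosslink_sites)) {
    for (nm in names(cfg$crosslink_sites)) {
      sites[[nm]] <- as.integer(cfg$crosslink_sites[[nm]])
    }
  }
  sites
}

#' Simulate CRAC-like reads with a ground-truth manifest
#'
#' For each read: a feature is drawn by class weight (optionally tilted by
#' per-feature weights), a template is chosen (unspliced precursor vs mature
#' RNA), a start is drawn from the positional profile, the template sequence
#' is copied with substitution errors, a microdeletion is introduced at a
#' covered crosslink site with probability `delete_prob`, a non-templated
#' oligo(A) tail of >= 2 nt is appended with the class's tail probability,
#' and the 3' adapter is appended when the insert is shorter than the cycle
#' length.  Every event is recorded in the manifest.
#'
#' @param genome A `crac_genome`.
#' @param features A `crac_features` table.
#' @param cfg A `sim_config`.
#' @return List with `reads` (data.frame `id`, `seq`) and `manifest`
#'   (data.frame, one row per read, with the resolved configuration in
#'   attributes `config` and `crosslink_sites`, the latter also mapped to
#'   genomic coordinates in attribute `crosslink_genomic`).
#' @export
simulate_reads <- function(genome, features, cfg) {
  validate_sim_config(cfg)
  set.seed(cfg$seed)
  minL <- cfg$read_length[1]; maxL <- cfg$read_length[2]

  span <- features$end - features$start
  usable <- span >= minL
  if (any(!usable)) {
    warning("skipping feature(s) shorter than the minimum read length: ",
            paste(features$id[!usable], collapse = ", "))
  }
  f_use <- features[usable, , drop = FALSE]
  cw <- cfg$class_weights[f_use$tx_class]
  cw[is.na(cw)] <- 0
  # per-feature multipliers redistribute mass within a class; class totals
  # stay at the configured class weights
  fw <- rep(1, nrow(f_use))
  if (!is.null(cfg$feature_weights)) {
    fw <- unname(cfg$feature_weights[f_use$id])
    fw[is.na(fw)] <- 1
  }
  fw_class_sum <- tapply(fw, f_use$tx_class, sum)
  w <- unname(cw) * fw / as.numeric(fw_class_sum[f_use$tx_class])
  if (sum(w) <= 0) stop("no feature receives positive sampling weight")
  w <- w / sum(w)

  sites <- resolve_crosslink_sites(features, cfg)
  empty <- data.frame(read_id = character(0), feature = character(0),
                      tx_class = character(0), template = character(0),
                      t_start = integer(0), raw_length = integer(0),
                      g_start = integer(0), g_end = integer(0),
                      del_pos = character(0), tail = character(0),
                      n_errors = integer(0), stringsAsFactors = FALSE)
  if (cfg$n_reads == 0L) {
    man <- empty
    attr(man, "config") <- cfg
    attr(man, "crosslink_sites") <- sites
    return(list(reads = data.frame(id = character(0), seq = character(0),
                                   stringsAsFactors = FALSE),
                manifest = man))
  }

  pick <- sample.int(nrow(f_use), cfg$n_reads, replace = TRUE, prob = w)
  ids <- sprintf("r%07d", seq_len(cfg$n_reads))
  seq_out <- character(cfg$n_reads)
  man_rows <- list()
  bases <- c("A", "C", "G", "T")

  for (fi in seq_len(nrow(f_use))) {
    idx <- which(pick == fi)
    if (!length(idx)) next
    f <- f_use[fi, ]
    m <- length(idx)
    # precursor flank (pre-tRNA leader/trailer style), clipped to the genome
    pf <- cfg$precursor_flank
    ext <- 0L
    if (!is.null(pf) && length(pf)) {
      ext <- if (is.null(names(pf))) as.integer(pf[1]) else {
        v <- pf[f$tx_class]; if (is.na(v)) 0L else as.integer(v)
      }
    }
    extL <- min(ext, f$start)
    extR <- min(ext, genome$lengths[[f$chrom]] - f$end)
    ext5 <- if (f$strand == "+") extL else extR # tx-5' extension length
    has_intron <- f$n_exons > 1L
    has_pre <- has_intron || extL + extR > 0L
    is_pre <- if (has_pre) stats::runif(m) < cfg$pre_mature_ratio else rep(FALSE, m)

    site_pre <- sites[[f$id]]
    # crosslink site in mature coordinates (NA if intronic)
    introns <- feature_introns(f)
    site_mat <- site_pre
    if (nrow(introns) > 0L && length(site_pre)) {
      pre_map <- template_map(f, "precursor")
      mat_map <- template_map(f, "mature")
      site_mat <- vapply(site_pre, function(s) {
        g <- pre_map[s + 1L]
        hit <- match(g, mat_map)
        if (is.na(hit)) NA_integer_ else hit - 1L
      }, integer(1))
    }
    pre_g <- seq.int(f$start - extL, f$end + extR - 1L)
    if (f$strand == "-") pre_g <- rev(pre_g)
    pre_seq <- genome_seq(genome, f$chrom, f$start - extL, f$end + extR)
    if (f$strand == "-") pre_seq <- revcomp(pre_seq)
    maps <- list(precursor = pre_g, mature = template_map(f, "mature"))
    seqs <- list(precursor = pre_seq,
                 mature = feature_sequence(genome, f, "mature"))

    for (tmpl in c("precursor", "mature")) {
      sel <- idx[if (tmpl == "precursor") is_pre else !is_pre]
      if (!length(sel)) next
      S <- seqs[[tmpl]]; Tn <- nchar(S); gmap <- maps[[tmpl]]
      tsites <- if (tmpl == "precursor") site_pre + ext5 else
        site_mat[!is.na(site_mat)]
      mm <- length(sel)
      L <- minL + sample.int(maxL - minL + 1L, mm, replace = TRUE) - 1L
      L <- pmin(L, Tn)
      start <- integer(mm)
      use_peak <- stats::runif(mm) < cfg$peak_frac & length(tsites) > 0L
      if (any(use_peak)) {
        s0 <- tsites[1L]
        st <- round(stats::rnorm(sum(use_peak), s0 - L[use_peak] / 2, cfg$peak_width))
        start[use_peak] <- pmax(0L, pmin(as.integer(st), Tn - L[use_peak]))
      }
      if (any(!use_peak)) {
        nu <- sum(!use_peak)
        start[!use_peak] <- as.integer(floor(stats::runif(nu) * (Tn - L[!use_peak] + 1L)))
      }
      sq <- substring(S, start + 1L, start + L)
      delrec <- character(mm)

      # microdeletions at covered crosslink sites
      if (cfg$delete_prob > 0 && length(tsites)) {
        for (s0 in tsites) {
          cov <- which(start <= s0 & s0 < start + L)
          if (!length(cov)) next
          hit <- cov[stats::runif(length(cov)) < cfg$delete_prob]
          for (ii in hit) {
            dlen <- sample.int(2L, 1L, prob = cfg$del_len_probs)
            dlen <- min(dlen, start[ii] + L[ii] - s0)
            r <- s0 - start[ii] # 0-based offset in read
            sq[ii] <- paste0(substr(sq[ii], 1L, r),
                             substr(sq[ii], r + dlen + 1L, nchar(sq[ii])))
            gpos <- sort(gmap[(s0:(s0 + dlen - 1L)) + 1L])
            delrec[ii] <- if (nzchar(delrec[ii])) {
              paste(delrec[ii], paste(gpos, collapse = ","), sep = ",")
            } else paste(gpos, collapse = ",")
          }
        }
      }

      # substitution errors
      nerr <- stats::rbinom(mm, nchar(sq), cfg$seq_error)
      for (ii in which(nerr > 0L)) {
        p <- sample.int(nchar(sq[ii]), nerr[ii])
        ch <- strsplit(sq[ii], "")[[1L]]
        for (pp in p) ch[pp] <- sample(setdiff(bases, ch[pp]), 1L)
        sq[ii] <- paste(ch, collapse = "")
      }

      # antisense contamination (strand-flipped copy, no tail)
      anti <- stats::runif(mm) < cfg$antisense_rate
      if (any(anti)) sq[anti] <- revcomp(sq[anti])

      # non-templated oligo(A) tails (>= 2 nt)
      piA <- class_tail_prob(cfg, f$tx_class)
      tailed <- stats::runif(mm) < piA & !anti
      tails <- character(mm)
      if (any(tailed)) {
        k <- 2L + stats::rgeom(sum(tailed), cfg$tail_geom_p)
        tails[tailed] <- strrep("A", k)
        sq[tailed] <- paste0(sq[tailed], tails[tailed])
      }

      # adapter read-through up to the cycle length
      short <- nchar(sq) < maxL
      if (any(short)) {
        sq[short] <- substr(paste0(sq[short], cfg$adapter), 1L, maxL)
      }

      seq_out[sel] <- sq
      g1 <- gmap[start + 1L]; g2 <- gmap[start + L]
      man_rows[[length(man_rows) + 1L]] <- data.frame(
        read_id = ids[sel], feature = f$id, tx_class = f$tx_class,
        template = if (has_pre) tmpl else "mature",
        t_start = start, raw_length = L,
        g_start = pmin(g1, g2), g_end = pmax(g1, g2) + 1L,
        del_pos = delrec, tail = tails, n_errors = nerr,
        stringsAsFactors = FALSE)
    }
  }

  manifest <- do.call(rbind, c(list(empty), man_rows))
  manifest <- manifest[order(manifest$read_id), , drop = FALSE]
  rownames(manifest) <- NULL
  attr(manifest, "config") <- cfg
  attr(manifest, "crosslink_sites") <- sites
  gsite <- lapply(stats::setNames(seq_len(nrow(features)), features$id), function(i) {
    m <- template_map(features[i, ], "precursor")
    s <- sites[[features$id[i]]]
    if (length(s)) m[s + 1L] else integer(0)
  })
  attr(manifest, "crosslink_genomic") <- gsite
  list(reads = data.frame(id = ids, seq = seq_out, stringsAsFactors = FALSE),
       manifest = manifest)
}

#' Write reads as FASTQ (Phred+33, constant quality)
#'
#' @param reads Data.frame with columns `id`, `seq`.
#' @param path Output FASTQ path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  ss <- Biostrings::DNAStringSet(reads$seq)
  names(ss) <- reads$id
  qual <- Biostrings::BStringSet(strrep("I", nchar(reads$seq)))
  Biostrings::writeXStringSet(ss, path, format = "fastq", qualities = qual)
  invisible(path)
}

#' Read a FASTQ file into a reads table
#'
#' @param path FASTQ path.
#' @return Data.frame with columns `id`, `seq`.
#' @export
read_fastq <- function(path) {
  ss <- Biostrings::readDNAStringSet(path, format = "fastq")
  data.frame(id = sub("\\s.*$", "", names(ss)), seq = as.character(ss),
             stringsAsFactors = FALSE)
}

#' Write a truth manifest as JSON lines
#'
#' @param manifest Manifest data.frame from [simulate_reads()].
#' @param path Output path (one JSON object per read).
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(vapply(seq_len(nrow(manifest)), function(i) {
    jsonlite::toJSON(as.list(manifest[i, , drop = FALSE]), auto_unbox = TRUE)
  }, character(1)), con)
  invisible(path)
}
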