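test_that("hit and deletion pileups place hpm mass on the covered bases", {
  g <- new_genome(c(chrP = strrep("ACGT", 25)))
  one <- make_aln("r1", "chrP", "+", 0L, "10M")
  trk <- pileup(one, g, "chrP", kind = "hits")
  expect_equal(trk$values[1:10], rep(1e6, 10))
  expect_equal(sum(trk$values), 1e7)

  dd <- make_aln("r1", "chrP", "+", 0L, "4M2D4M")
  hits <- pileup(dd, g, "chrP", kind = "hits")
  dels <- pileup(dd, g, "chrP", kind = "dels")
  expect_equal(dels$values[5:6], rep(1e6, 2))
  expect_equal(hits$values[5:6], c(0, 0))
  expect_equal(hits$values[c(1:4, 7:10)], rep(1e6, 8))

  expect_error(pileup(one, g, "chrMissing"), "unknown chromosome")
})

test_that("hits mass is conserved and the A-tailed track is bounded by the total", {
  s <- std_sim(n_reads = 2500L, seed = 29L, a_tail_prob = 0.3)
  tr <- trim_adapter(collapse_duplicates(s$reads), s$cfg$adapter)
  a <- align_reads(tr, s$genome)
  tc <- call_tails(a, s$genome, adapter = s$cfg$adapter)
  a <- tc$alignments
  counted <- a[!a$multi, ]
  total <- pileup(a, s$genome, "chrS", kind = "hits")
  w <- 1e6 / nrow(counted)
  mlen <- sum(vapply(cigar_ops(counted$cigar), function(o) {
    sum(o$len[o$op == "M"])
  }, numeric(1)))
  expect_equal(sum(total$values), mlen * w, tolerance = 1e-9)

  atail <- pileup(a, s$genome, "chrS", kind = "hits", filter = "a_tailed",
                  tails = tc$tails, total_mapped = nrow(counted))
  expect_true(all(atail$values <= total$values + 1e-9))
})

test_that("deletion mass tracks the simulated deletion rate", {
  s <- std_sim(n_reads = 6000L, seed = 37L, delete_prob = 0.3, seq_error = 0,
               read_length = c(30L, 50L), peak_frac = 1, peak_width = 3)
  tr <- trim_adapter(collapse_duplicates(s$reads), s$cfg$adapter,
                     max_mismatch = 0L)
  a <- align_reads(tr, s$genome)
  hits <- pileup(a, s$genome, "chrS", kind = "hits")
  dels <- pileup(a, s$genome, "chrS", kind = "dels")
  # expected dels/hits ratio: delta x P(cover site) x mean del length / read length
  man <- s$manifest
  truth_ratio <- sum(nchar(gsub("[^,]", "", man$del_pos)) + nzchar(man$del_pos)) /
    sum(man$raw_length)
  got_ratio <- sum(dels$values) / sum(hits$values)
  expect_lt(abs(got_ratio - truth_ratio) / truth_ratio, 0.2)
})

test_that("metagene rows anchor at the 3' splice site ordered by intron length", {
  g <- new_genome(c(chrM = strrep("ACGT", 500)))
  f <- new_features(
    c("long_i", "short_i"), "chrM", "+",
    list(rbind(c(100L, 200L), c(600L, 800L)),   # intron 400
         rbind(c(1000L, 1100L), c(1200L, 1400L))), # intron 100
    c("mRNA", "mRNA"))
  # reads only in exon 2 of long_i
  aln <- make_aln(sprintf("r%d", 1:5), "chrM", "+",
                  start = seq(620L, 700L, 20L), cigar = "30M")
  mg <- metagene_3ss(aln, g, f, window = c(100L, 100L))
  expect_identical(rownames(mg$matrix), c("long_i", "short_i"))
  expect_identical(mg$meta$intron_length, c(400L, 100L))
  left <- mg$matrix["long_i", as.integer(colnames(mg$matrix)) < 0]
  right <- mg$matrix["long_i", as.integer(colnames(mg$matrix)) >= 0]
  expect_equal(sum(left), 0)
  expect_gt(sum(right), 0)

  intronless <- new_features("plain", "chrM", "+", list(rbind(c(0L, 500L))),
                             "mRNA")
  expect_error(metagene_3ss(aln, g, intronless), "no spliced")
})

test_that("higher-weighted long-intron genes show proportionally higher metagene mass", {
  fg <- forge_genome(seed = 41)
  f <- fg$features
  spliced <- f[f$tx_class == "mRNA" & f$n_exons > 1, ]
  long_ids <- spliced$id[grepl("mRL", spliced$id)]
  fw <- stats::setNames(ifelse(grepl("mRL", f$id), 3, 1), f$id)
  cfg <- sim_config(n_reads = 20000L, seed = 43L, class_weights = c(mRNA = 1),
                    feature_weights = fw, seq_error = 0)
  sim <- simulate_reads(fg$genome, f, cfg)
  j <- build_junction_library(f, fg$genome, flank = 50L)
  tr <- trim_adapter(collapse_duplicates(sim$reads), cfg$adapter,
                     max_mismatch = 0L)
  al <- lift_junction_alignments(align_reads(tr, fg$genome, j), j, f)
  mg <- metagene_3ss(al, fg$genome, f, window = c(150L, 150L))
  rs <- rowSums(mg$matrix, na.rm = TRUE)
  ratio <- mean(rs[long_ids]) / mean(rs[setdiff(names(rs), long_ids)])
  expect_gt(ratio, 1.8) # 3x sampling weight, duplicate collapse damps it
})

test_that("tRNA profiles are 5'-anchored, length-ranked and expose precursor flanks", {
  g <- new_genome(c(chrN = strrep("ACGT", 200)))
  f <- new_features(
    c("t_long", "t_short"), "chrN", "+",
    list(rbind(c(100L, 140L), c(160L, 200L)), rbind(c(400L, 480L))),
    c("tRNA", "tRNA"))
  inside <- make_aln("r1", "chrN", "+", 405L, "30M")
  tp <- trna_profile(inside, g, f, flank = 20L)
  expect_identical(rownames(tp$matrix), c("t_long", "t_short"))
  prof <- tp$matrix["t_short", ]
  pos <- as.integer(colnames(tp$matrix))
  expect_true(all(prof[pos < 0] == 0, na.rm = TRUE))
  expect_gt(sum(prof[pos >= 0], na.rm = TRUE), 0)

  trailer <- make_aln("r2", "chrN", "+", 470L, "25M") # 15 nt past the 3' end
  tp2 <- trna_profile(trailer, g, f, flank = 20L)
  prof2 <- tp2$matrix["t_short", ]
  expect_gt(sum(prof2[pos >= 80], na.rm = TRUE), 0)

  # intron-covering precursor read registers inside the intron span
  intronic <- make_aln("r3", "chrN", "+", 142L, "15M")
  tp3 <- trna_profile(intronic, g, f, flank = 20L)
  irel <- tp3$meta$intron_rel_start[tp3$meta$id == "t_long"]
  expect_identical(irel, 40L)
  expect_gt(sum(tp3$matrix["t_long", pos >= irel & pos < irel + 20],
                na.rm = TRUE), 0)
})

test_that("bedGraph export writes compact runs and round-trips through rtracklayer", {
  g <- new_genome(c(chrP = strrep("ACGT", 25)))
  trk <- structure(list(chrom = "chrP", strand = "+", kind = "hits",
                        filter = "total",
                        values = c(rep(0, 10), rep(1e6, 10), rep(0, 80))),
                   class = "crac_track")
  bg <- withr::local_tempfile(fileext = ".bedgraph")
  write_bedgraph(trk, bg)
  lines <- readLines(bg)
  expect_identical(length(lines), 2L) # header + one run
  expect_identical(lines[2], "chrP\t10\t20\t1000000")
  expect_equal(read_bedgraph(bg, g, "chrP"), trk$values)

  empty <- trk; empty$values <- rep(0, 100)
  write_bedgraph(empty, bg)
  expect_identical(length(readLines(bg)), 1L) # header only
})
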