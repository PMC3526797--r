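make_single_intron_world <- function() {
  g <- new_genome(c(chrS = strrep("ACGT", 250)))
  f <- new_features("sp", "chrS", "+",
                    list(rbind(c(100L, 300L), c(500L, 700L))), "mRNA")
  j <- build_junction_library(f, g, flank = 50L)
  list(genome = g, features = f, junctions = j)
}

test_that("junction counting honors the min_overhang rule on both IE and EE", {
  w <- make_single_intron_world()
  # IE3 boundary at 500: one read with 5 nt on each side, one ending exactly there
  aln <- make_aln(c("ie_ok", "ie_stop"), "chrS", "+",
                  start = c(495L, 480L), cigar = c("10M", "20M"))
  at <- assign_features(aln, w$features)
  jc <- count_junctions(aln, w$junctions, w$features, at)
  expect_equal(jc$per_gene$IE3[1], 1) # only the spanning read
  expect_equal(jc$per_gene$IE5[1], 0)

  # EE requires a junction-library alignment crossing the splice
  ee_read <- make_aln("ee1", junction_names(w$junctions[w$junctions$kind == "EE", ]),
                      "+", 40L, "20M", origin = "junction")
  ee_l <- lift_junction_alignments(ee_read, w$junctions, w$features)
  at2 <- assign_features(ee_l, w$features)
  jc2 <- count_junctions(ee_l, w$junctions, w$features, at2)
  expect_equal(jc2$per_gene$EE[1], 1)

  # an entry alignment stopping at the boundary does not count
  ee_stop <- make_aln("ee2", junction_names(w$junctions[w$junctions$kind == "EE", ]),
                      "+", 30L, "20M", origin = "junction")
  ee_sl <- lift_junction_alignments(ee_stop, w$junctions, w$features)
  jc3 <- count_junctions(ee_sl, w$junctions, w$features,
                         assign_features(ee_sl, w$features))
  expect_equal(jc3$per_gene$EE[1], 0)
})

test_that("a symmetric 1:1 pre:mature mix gives IE/EE near two", {
  w <- make_single_intron_world()
  # tile precursor reads across both IE boundaries and mature reads across EE,
  # one read per offset: per-read classification is the direct oracle
  pre_starts <- c(480:499, 485:499 + 16)  # spanning 500 (IE3)
  pre5 <- c(280:299, 301:315)             # spanning 300 (IE5)
  pre_aln <- make_aln(sprintf("p%03d", seq_along(c(pre_starts, pre5))),
                      "chrS", "+", c(pre_starts, pre5), "21M")
  ee <- w$junctions[w$junctions$kind == "EE", ]
  mat_off <- 30:64 # entry offsets crossing flank_up = 50 with 21M
  ee_aln <- make_aln(sprintf("m%03d", seq_along(mat_off)),
                     junction_names(ee), "+", mat_off, "21M",
                     origin = "junction")
  ee_l <- lift_junction_alignments(ee_aln, w$junctions, w$features)
  all_aln <- rbind(pre_aln, ee_l[, names(pre_aln)])
  all_aln$junc_feature <- c(rep(NA_character_, nrow(pre_aln)), ee_l$junc_feature)
  all_aln$junc_kind <- c(rep(NA_character_, nrow(pre_aln)), ee_l$junc_kind)
  all_aln$junc_off <- c(rep(NA_integer_, nrow(pre_aln)), ee_l$junc_off)
  all_aln$junc_flank_up <- c(rep(NA_integer_, nrow(pre_aln)), ee_l$junc_flank_up)
  class(all_aln) <- c("crac_alignments", "data.frame")
  at <- assign_features(all_aln, w$features)
  jc <- count_junctions(all_aln, w$junctions, w$features, at)
  # direct oracle: count spanning reads per junction kind
  n_ie <- sum(pre_starts < 500 & pre_starts + 21 > 500) +
    sum(pre5 < 300 & pre5 + 21 > 300)
  n_ee <- sum(mat_off < 50 & mat_off + 21 > 50)
  expect_equal(jc$totals[["IE"]], n_ie)
  expect_equal(jc$totals[["EE"]], n_ee)
  expect_equal(jc$totals[["IE_EE"]], n_ie / n_ee)
  expect_gt(jc$totals[["IE_EE"]], 1.7)
  expect_lt(jc$totals[["IE_EE"]], 2.3)
})

test_that("ratio and SE behave across replicates and bootstrap for r = 1", {
  r1 <- ratio_with_se(c(4, 4), c(2, 2))
  expect_equal(r1$ratio, 2)
  expect_equal(r1$se, 0)

  r2 <- ratio_with_se(c(1, 3), c(1, 1))
  expect_equal(r2$ratio, 2)
  expect_equal(r2$se, 1) # sd = sqrt(2), se = sd / sqrt(2)

  expect_warning(r3 <- ratio_with_se(c(1, 3), c(1, 0)), "zero denominator")
  expect_equal(r3$ratio, 1)

  bu <- withr::with_seed(9, data.frame(num = rpois(50, 4),
                                       den = rpois(50, 8) + 1))
  r4 <- ratio_with_se(sum(bu$num), sum(bu$den), boot_units = bu, seed = 2)
  expect_true(is.finite(r4$se) && r4$se > 0)
  r4b <- ratio_with_se(sum(bu$num), sum(bu$den), boot_units = bu, seed = 2)
  expect_identical(r4$se, r4b$se)
})

test_that("splice-site preference is 1 under uniform coverage and 0 without 3'SS reads", {
  w <- make_single_intron_world()
  # uniform tiling across the whole gene: every base equally covered
  starts <- seq(80L, 700L, 1L)
  aln <- make_aln(sprintf("u%04d", seq_along(starts)), "chrS", "+", starts, "20M")
  ss <- ss_preference(aln, w$genome, w$junctions, window = 10L)
  expect_equal(ss$ratio, 1, tolerance = 1e-9)

  only5 <- make_aln(sprintf("v%02d", 1:10), "chrS", "+",
                    rep(292L, 10), "16M") # covers only the 5'SS window
  ss2 <- ss_preference(only5, w$genome, w$junctions, window = 10L)
  expect_equal(ss2$ratio, 0)

  no_spliced <- w$junctions[0, ]
  expect_error(ss_preference(aln, w$genome, no_spliced), "no spliced")
})

test_that("IE/EE rises strictly with the precursor fraction in simulation", {
  fg <- forge_genome(seed = 7)
  j <- build_junction_library(fg$features, fg$genome, flank = 50L)
  ratios <- vapply(c(0.15, 0.5, 0.85), function(p) {
    cfg <- sim_config(n_reads = 15000L, seed = 47L, pre_mature_ratio = p,
                      class_weights = c(mRNA = 1))
    sim <- simulate_reads(fg$genome, fg$features, cfg)
    tr <- trim_adapter(collapse_duplicates(sim$reads), cfg$adapter)
    al <- lift_junction_alignments(align_reads(tr, fg$genome, j), j, fg$features)
    at <- assign_features(al, fg$features)
    count_junctions(al, j, fg$features, at)$totals[["IE_EE"]]
  }, numeric(1))
  expect_true(all(diff(ratios) > 0))
})
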