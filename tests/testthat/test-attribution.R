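test_that("attribution follows class priority, flanks and intergenic fallback", {
  g <- new_genome(c(chrA = strrep("ACGT", 300), chrB = strrep("ACGT", 100)))
  f <- new_features(
    id = c("host_mRNA", "nested_sno", "trn1"),
    chrom = c("chrA", "chrA", "chrB"),
    strand = c("+", "+", "+"),
    exons = list(rbind(c(0L, 200L), c(600L, 800L)),
                 rbind(c(300L, 400L)),
                 rbind(c(10L, 90L))),
    tx_class = c("mRNA", "snoRNA", "tRNA"))

  aln <- make_aln(
    c("in_sno", "in_exon", "in_intron", "nowhere", "past_trna"),
    chrom = c("chrA", "chrA", "chrA", "chrA", "chrB"),
    strand = "+",
    start = c(320L, 50L, 450L, 1050L, 100L),
    cigar = c("30M", "30M", "30M", "30M", "20M"))
  at <- assign_features(aln, f, flank = 50L)

  expect_identical(at$feature[at$read_id == "in_sno"], "nested_sno")
  expect_identical(at$tx_class[at$read_id == "in_sno"], "snoRNA")
  expect_identical(at$region[at$read_id == "in_exon"], "exon")
  expect_identical(at$region[at$read_id == "in_intron"], "intron")
  expect_identical(at$feature[at$read_id == "nowhere"], "intergenic")
  # read 10-30 nt past the tRNA 3' end, within the 50 nt flank
  expect_identical(at$feature[at$read_id == "past_trna"], "trn1")
  expect_identical(at$region[at$read_id == "past_trna"], "3'-flank")
})

test_that("class distribution percentages partition the counted reads", {
  at <- data.frame(read_id = sprintf("r%d", 1:4),
                   feature = c("t1", "t2", "m1", "m2"),
                   tx_class = c("tRNA", "tRNA", "mRNA", "mRNA"),
                   polymerase = c("PolIII", "PolIII", "PolII", "PolII"),
                   region = "exon", count = c(1L, 1L, 1L, 1L),
                   stringsAsFactors = FALSE)
  cd <- class_distribution(at)
  expect_equal(cd[["tRNA"]], 50)
  expect_equal(cd[["mRNA"]], 50)
  expect_equal(sum(cd), 100, tolerance = 1e-9)

  one <- class_distribution(at[at$tx_class == "tRNA", ])
  expect_equal(one[["tRNA"]], 100)
  expect_error(class_distribution(at[0, ]), "no counted")

  # count weighting recovers multiplicity
  at$count <- c(3L, 1L, 1L, 1L)
  expect_equal(class_distribution(at, weight = "count")[["tRNA"]], 100 * 4 / 6)
})

test_that("polymerase partition sums to one and puts U6 in Pol III", {
  at <- data.frame(read_id = sprintf("r%d", 1:3),
                   feature = c("r35", "m1", "r5"),
                   tx_class = c("rRNA_35S", "mRNA", "rRNA_5S"),
                   polymerase = c("PolI", "PolII", "PolIII"),
                   region = "exon", count = 1L, stringsAsFactors = FALSE)
  pp <- polymerase_partition(at)
  expect_equal(unname(pp), rep(1 / 3, 3))

  u6 <- at[1, ]; u6$tx_class <- "snRNA"
  u6$polymerase <- class_polymerase("snRNA", "PolIII")
  expect_equal(polymerase_partition(u6)[["PolIII"]], 1)

  trna <- at; trna$polymerase <- "PolIII"
  expect_equal(polymerase_partition(trna)[["PolIII"]], 1)
})

test_that("A-tail frequency table stratifies by polymerase with NA for empty strata", {
  n <- 100
  at <- data.frame(read_id = sprintf("r%03d", 1:n), feature = "f",
                   tx_class = "mRNA", polymerase = "PolII", region = "exon",
                   count = 1L, stringsAsFactors = FALSE)
  tails <- data.frame(read_id = at$read_id, tail = "", n_A = 0L,
                      a_tailed = c(rep(TRUE, 10), rep(FALSE, 90)),
                      first_A_coord = NA_integer_, stringsAsFactors = FALSE)
  tab <- atail_frequency_table(at, tails)
  expect_equal(tab$fraction[tab$stratum == "total"], 0.10)
  expect_equal(tab$fraction[tab$stratum == "PolII"], 0.10)
  expect_true(is.na(tab$fraction[tab$stratum == "PolI"]))
})

test_that("per-RNA hpm columns are exact per-million partitions", {
  f <- new_features(c("F", "G"), "chr", "+",
                    list(rbind(c(0L, 100L)), rbind(c(200L, 300L))),
                    c("mRNA", "mRNA"))
  at <- data.frame(read_id = sprintf("r%d", 1:10),
                   feature = c(rep("F", 5), rep("G", 3), rep("intergenic", 2)),
                   tx_class = "mRNA", polymerase = "PolII", region = "exon",
                   count = 1L, stringsAsFactors = FALSE)
  m <- per_rna_counts(list(exp1 = at), f)
  expect_equal(m["F", "exp1"], 5e5)
  expect_equal(m["G", "exp1"], 3e5)
  expect_equal(m["intergenic", "exp1"], 2e5)
  expect_equal(unname(colSums(m)), 1e6, tolerance = 1e-9)
})

test_that("replicate simulations give highly correlated per-RNA columns", {
  fg <- forge_genome(seed = 7)
  j <- build_junction_library(fg$features, fg$genome, flank = 50L)
  ats <- lapply(c(61L, 62L), function(sd) {
    cfg <- sim_config(n_reads = 12000L, seed = sd)
    sim <- simulate_reads(fg$genome, fg$features, cfg)
    tr <- trim_adapter(collapse_duplicates(sim$reads), cfg$adapter)
    al <- lift_junction_alignments(align_reads(tr, fg$genome, j), j, fg$features)
    assign_features(al, fg$features)
  })
  names(ats) <- c("rep1", "rep2")
  m <- per_rna_counts(ats, fg$features)
  expect_gt(stats::cor(m[, 1], m[, 2]), 0.95)
})
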