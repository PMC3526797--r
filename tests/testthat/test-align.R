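ali <- function(seqs, genome, junctions = NULL, ...) {
  align_reads(data.frame(id = sprintf("r%03d", seq_along(seqs)), seq = seqs,
                         stringsAsFactors = FALSE), genome, junctions, ...)
}

test_that("exact, gapped and tailed reads produce the expected alignments", {
  fg <- forge_genome(counts = c(mRNA = 2), seed = 31)
  g <- fg$genome
  s <- g$seq[[1]]

  exact <- substr(s, 101, 130)
  a <- ali(exact, g)
  expect_identical(a$start, 100L)
  expect_identical(a$cigar, "30M")
  expect_identical(a$soft3, "")
  expect_identical(a$score, 30L)

  gapped <- paste0(substr(s, 101, 110), substr(s, 113, 130))
  a2 <- ali(gapped, g)
  expect_identical(a2$start, 100L)
  expect_identical(a2$cigar, "10M2D18M")
  expect_identical(a2$score, 28L - 3L)
  expect_identical(a2$score, oracle_align_score(gapped, g))

  tailed <- paste0(substr(s, 101, 120), "AAAA")
  if (substr(s, 121, 121) != "A") { # guaranteed clip when downstream is not A
    a3 <- ali(tailed, g)
    expect_identical(a3$cigar, "20M4S")
    expect_identical(a3$soft3, "AAAA")
  }
})

test_that("minus-strand reads map with forward coordinates and read-3' soft clips", {
  fg <- forge_genome(counts = c(mRNA = 2), seed = 33)
  g <- fg$genome
  s <- g$seq[[1]]
  # choose a window whose upstream genomic base is not T, so an appended
  # oligo(A) cannot be absorbed on the minus strand
  pos <- 201L
  while (substr(s, pos - 1L, pos - 1L) == "T") pos <- pos + 7L
  seg <- substr(s, pos, pos + 34)
  a <- ali(revcomp(seg), g)
  expect_identical(a$strand, "-")
  expect_identical(a$start, pos - 1L)
  expect_identical(a$cigar, "35M")

  # 3' tail on a minus-strand read appears as a leading S in reference order
  tailed <- paste0(revcomp(seg), "AAAA")
  a2 <- ali(tailed, g)
  expect_identical(a2$strand, "-")
  expect_identical(a2$soft3, "AAAA")
  expect_identical(a2$cigar, "4S35M")
})

test_that("repeated loci are flagged multi; unseedable reads stay unmapped", {
  base <- withr::with_seed(1, paste(sample(c("A", "C", "G", "T"), 200,
                                           replace = TRUE), collapse = ""))
  rep_seg <- substr(base, 1, 40)
  g <- new_genome(c(chrR = paste0(base, "TTTTCCCC", rep_seg)))
  a <- ali(substr(rep_seg, 5, 30), g)
  expect_true(a$multi)
  nohit <- ali(strrep("N", 30), g)
  expect_identical(nrow(nohit), 0L)
  expect_identical(attr(nohit, "n_unmapped"), 1L)
})

test_that("junction-spanning reads align to EE entries and lift to M-N-M", {
  fg <- forge_genome(counts = c(mRNA_spliced_long = 2), seed = 35)
  g <- fg$genome
  f <- fg$features
  j <- build_junction_library(f, g, flank = 50L)
  fi <- f[1, ]
  mat <- feature_sequence(g, fi, "mature")
  anchor <- j$mat_anchor[j$feature == fi$id & j$kind == "EE"]
  read <- substr(mat, anchor - 14, anchor + 15) # 15 nt each side of the junction
  a <- ali(read, g, j)
  expect_identical(a$origin, "junction")
  al <- lift_junction_alignments(a, j, f)
  expect_identical(al$chrom, fi$chrom)
  expect_match(al$cigar, "^15M\\d+N15M$")
  introns <- feature_introns(fi)
  expect_identical(cigar_ref_span(al$cigar),
                   30L + (introns[1, 2] - introns[1, 1]))
})

test_that("read sequences are conserved: genome M bases + soft3 reconstruct the read", {
  s <- std_sim(n_reads = 400L, seed = 13L, seq_error = 0, delete_prob = 0)
  tr <- trim_adapter(collapse_duplicates(s$reads), s$cfg$adapter,
                     max_mismatch = 0L)
  a <- align_reads(tr, s$genome)
  for (i in seq_len(min(nrow(a), 200L))) {
    o <- cigar_ops(a$cigar[i])[[1]]
    pos <- a$start[i]
    parts <- character(0)
    for (r in seq_len(nrow(o))) {
      if (o$op[r] == "M") {
        parts <- c(parts, genome_seq(s$genome, a$chrom[i], pos, pos + o$len[r]))
      }
      if (o$op[r] %in% c("M", "D", "N")) pos <- pos + o$len[r]
    }
    body <- paste(parts, collapse = "")
    if (a$strand[i] == "-") body <- revcomp(body)
    recon <- paste0(body, a$soft3[i])
    target <- tr$seq[tr$id == a$read_id[i]]
    expect_identical(nchar(recon), nchar(target), info = a$read_id[i])
    mm <- sum(strsplit(recon, "")[[1]] != strsplit(target, "")[[1]])
    expect_lte(mm, 2) # M ops may carry recorded mismatches
    expect_identical(a$soft3[i],
                     substr(target, nchar(target) - nchar(a$soft3[i]) + 1L,
                            nchar(target)))
  }
})

test_that("mapped fraction does not increase with the substitution error rate", {
  rates <- c(0, 0.01, 0.05)
  mapped <- vapply(rates, function(e) {
    s <- std_sim(n_reads = 1500L, seed = 17L, seq_error = e)
    tr <- trim_adapter(collapse_duplicates(s$reads), s$cfg$adapter)
    a <- align_reads(tr, s$genome)
    nrow(a) / (nrow(a) + attr(a, "n_unmapped"))
  }, numeric(1))
  expect_true(all(diff(mapped) <= 0))
})

test_that("SAM export/import round-trips representable records", {
  s <- std_sim(n_reads = 300L, seed = 19L)
  tr <- trim_adapter(collapse_duplicates(s$reads), s$cfg$adapter)
  j <- build_junction_library(s$features, s$genome, flank = 50L)
  a <- lift_junction_alignments(align_reads(tr, s$genome, j), j, s$features)
  sam <- withr::local_tempfile(fileext = ".sam")
  write_sam(a, s$genome, sam, reads = tr)
  b <- read_sam(sam)
  expect_identical(nrow(b), nrow(a))
  for (col in c("read_id", "chrom", "strand", "start", "cigar", "count",
                "soft3")) {
    expect_identical(b[[col]], a[[col]], info = col)
  }
  expect_identical(b$multi, a$multi)
})

test_that("SAM parsing converts POS and rejects unsupported CIGARs", {
  sam <- withr::local_tempfile(fileext = ".sam")
  hdr <- c("@HD\tVN:1.6", "@SQ\tSN:chrZ\tLN:1000")
  writeLines(c(hdr, "q1\t0\tchrZ\t101\t255\t5M1D5M\t*\t0\t0\tACGTACGTAC\t*"), sam)
  a <- read_sam(sam)
  expect_identical(a$start, 100L)
  expect_identical(a$cigar, "5M1D5M")

  writeLines(c(hdr, "q2\t0\tchrZ\t101\t255\t5M2H\t*\t0\t0\tACGTA\t*"), sam)
  expect_error(read_sam(sam), "hard-clip")

  writeLines(c(hdr, "q3\t0\tchrZ\t101\t255\t3=2X\t*\t0\t0\tACGTA\t*"), sam)
  expect_identical(read_sam(sam)$cigar, "3M2M")
})

test_that("aligner matches the exhaustive single-gap oracle on controlled reads", {
  fg <- forge_genome(counts = c(mRNA = 2, tRNA = 2), seed = 13,
                     spacer = c(80L, 150L))
  g <- fg$genome
  gl <- g$lengths[[1]]
  withr::with_seed(4, {
    reads <- vapply(1:60, function(i) {
      st <- sample(gl - 60, 1)
      L1 <- sample(14:20, 1); dl <- sample(1:3, 1); L2 <- sample(10:20, 1)
      paste0(substr(g$seq[[1]], st, st + L1 - 1),
             substr(g$seq[[1]], st + L1 + dl, st + L1 + dl + L2 - 1))
    }, character(1))
  })
  a <- ali(reads, g)
  osc <- oracle_align_scores(reads, g)
  m <- match(sprintf("r%03d", seq_along(reads)), a$read_id)
  expect_true(all(!is.na(a$score[m]) & a$score[m] == osc))
})
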