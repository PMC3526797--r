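test_that("load_genome reads, sanitizes and validates FASTA", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chrI", "ACGT"), fa)
  g <- load_genome(fa)
  expect_identical(unname(g$lengths["chrI"]), 4L)
  expect_identical(g$seq[["chrI"]], "ACGT")

  writeLines(c(">chrI", "acgt"), fa)
  expect_identical(load_genome(fa)$seq[["chrI"]], "ACGT")

  writeLines(c(">chrI", "ACRGT"), fa)
  expect_identical(load_genome(fa)$seq[["chrI"]], "ACNGT")

  writeLines(c(">chrI", "ACGT", ">chrI", "GGGG"), fa)
  expect_error(load_genome(fa), "duplicate")

  writeLines(character(0), fa)
  expect_error(load_genome(fa), "empty")
})

test_that("GFF3 coordinates convert to 0-based half-open and introns derive", {
  g <- new_genome(c(chrI = strrep("ACGT", 20)))
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chrI\tsrc\ttranscript\t11\t40\t.\t+\t.\tID=tx1;tx_class=mRNA",
    "chrI\tsrc\texon\t11\t20\t.\t+\t.\tID=tx1.e1;Parent=tx1",
    "chrI\tsrc\texon\t31\t40\t.\t+\t.\tID=tx1.e2;Parent=tx1"
  ), gff)
  f <- load_annotation(gff, g)
  expect_identical(f$start, 10L)
  expect_identical(f$end, 40L)
  expect_equal(unname(f$exons[[1]]), rbind(c(10L, 20L), c(30L, 40L)))
  expect_equal(unname(feature_introns(f[1, ])), cbind(20L, 30L))
})

test_that("tRNA with two exons gets intron boundaries and Pol III", {
  g <- new_genome(c(chrI = strrep("ACGT", 30)))
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chrI\tsrc\ttranscript\t1\t100\t.\t+\t.\tID=t1;tx_class=tRNA",
    "chrI\tsrc\texon\t1\t37\t.\t+\t.\tID=t1.e1;Parent=t1",
    "chrI\tsrc\texon\t58\t100\t.\t+\t.\tID=t1.e2;Parent=t1"
  ), gff)
  f <- load_annotation(gff, g)
  expect_identical(f$polymerase, "PolIII")
  expect_equal(unname(feature_introns(f[1, ])), cbind(37L, 57L))
})

test_that("unknown classes warn and sink to other; out-of-bounds errors name the feature", {
  g <- new_genome(c(chrI = "ACGTACGTAC"))
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chrI\tsrc\ttranscript\t1\t5\t.\t+\t.\tID=x1;tx_class=weird"), gff)
  expect_warning(f <- load_annotation(gff, g), "other")
  expect_identical(f$tx_class, "other")

  writeLines(c("##gff-version 3",
               "chrI\tsrc\ttranscript\t5\t20\t.\t+\t.\tID=far;tx_class=mRNA"), gff)
  expect_error(load_annotation(gff, g), "far")
})

test_that("polymerase attribute overrides only where legitimate (U6 snRNA)", {
  expect_identical(class_polymerase("snRNA", "PolIII"), "PolIII")
  expect_identical(class_polymerase("snRNA"), "PolII")
  expect_error(class_polymerase("mRNA", "PolIII"), "inconsistent")
})

test_that("annotation write -> load round trip is identity", {
  fg <- forge_genome(seed = 19)
  gff <- withr::local_tempfile(fileext = ".gff3")
  write_annotation(fg$features, gff)
  f2 <- load_annotation(gff, fg$genome)
  for (col in c("id", "chrom", "strand", "start", "end", "tx_class",
                "polymerase", "gene_sets")) {
    expect_identical(f2[[col]], fg$features[[col]], info = col)
  }
  expect_identical(f2$exons, fg$features$exons)
})

test_that("junction library entries match direct string concatenation", {
  # exons [0,10) and [20,30): EE = last flank nt of exon1 + first of exon2
  g <- new_genome(c(chrJ = paste0("ACGTACGTAC", "GGGGGGGGGG", "TTCCTTCCTT")))
  f <- new_features("sp1", "chrJ", "+", list(rbind(c(0L, 10L), c(20L, 30L))),
                    "mRNA")
  j <- build_junction_library(f, g, flank = 2L)
  expect_identical(nrow(j), 3L)
  expect_setequal(j$kind, c("EE", "IE5", "IE3"))
  ee <- j[j$kind == "EE", ]
  expect_identical(ee$seq, paste0("AC", "TT")) # last 2 of exon1 + first 2 of exon2
  expect_identical(j$seq[j$kind == "IE5"], paste0("AC", "GG"))
  expect_identical(j$seq[j$kind == "IE3"], paste0("GG", "TT"))

  # intronless -> no entries; oversize flank truncates and flags
  f0 <- new_features("plain", "chrJ", "+", list(rbind(c(0L, 30L))), "mRNA")
  expect_identical(nrow(build_junction_library(f0, g, flank = 5L)), 0L)
  jt <- build_junction_library(f, g, flank = 15L)
  expect_true(all(jt$truncated))
})

test_that("EE entries reproduce the mature transcript locally, both strands", {
  fg <- forge_genome(seed = 23)
  f <- fg$features
  j <- build_junction_library(f, fg$genome, flank = 20L)
  ee <- j[j$kind == "EE", ]
  for (i in seq_len(nrow(ee))) {
    fi <- f[f$id == ee$feature[i], ]
    mat <- feature_sequence(fg$genome, fi, "mature")
    anchor <- ee$mat_anchor[i]
    local <- substr(mat, anchor - ee$flank_up[i] + 1L, anchor + ee$flank_down[i])
    expect_identical(ee$seq[i], local)
  }
})
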