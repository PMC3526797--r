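test_that("correlation distance matches the closed-form Pearson formula", {
  m <- rbind(a = c(1, 2, 3), b = c(1, 2, 3), c = c(3, 2, 1), d = c(1, 2, 4))
  d <- correlation_distance(m, log_transform = FALSE)
  expect_equal(d["a", "b"], 0)
  expect_equal(d["a", "c"], 2)
  # direct formula for rows (1,2,3) vs (1,2,4)
  x <- c(1, 2, 3); y <- c(1, 2, 4)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(d["a", "d"], 1 - r)
  expect_true(isSymmetric(unname(d)))
  expect_true(all(d >= 0 & d <= 2))
  expect_equal(unname(diag(d)), rep(0, 4))
})

test_that("zero-variance rows get unit distance and are flagged", {
  m <- rbind(flat = c(5, 5, 5), x = c(1, 2, 3), y = c(2, 1, 3))
  d <- correlation_distance(m, log_transform = FALSE)
  expect_equal(unname(d["flat", c("x", "y")]), c(1, 1))
  expect_identical(attr(d, "zero_variance"), "flat")
})

test_that("complete linkage agrees with a stepwise brute-force oracle", {
  brute_complete <- function(d) {
    # recompute max linkage between every cluster pair at every step
    cl <- as.list(seq_len(nrow(d)))
    heights <- numeric(0)
    members <- list()
    while (length(cl) > 1) {
      best <- c(Inf, NA, NA)
      for (i in seq_along(cl)) for (j in seq_len(i - 1)) {
        h <- max(d[cl[[i]], cl[[j]]])
        if (h < best[1]) best <- c(h, j, i)
      }
      heights <- c(heights, best[1])
      merged <- sort(c(cl[[best[2]]], cl[[best[3]]]))
      members[[length(members) + 1]] <- merged
      cl <- c(cl[-c(best[2], best[3])], list(merged))
    }
    list(heights = heights, members = members)
  }
  set.seed(11)
  for (rep in 1:5) {
    n <- 6
    m <- matrix(runif(n * n), n)
    d <- (m + t(m)) / 2; diag(d) <- 0
    rownames(d) <- colnames(d) <- letters[1:n]
    hc <- complete_linkage(d)
    bf <- brute_complete(d)
    expect_equal(hc$height, bf$heights, tolerance = 1e-12)
    got_members <- lapply(seq_len(n - 1), function(k) {
      sort(which(stats::cutree(hc, h = hc$height[k] + 1e-12) ==
                   stats::cutree(hc, h = hc$height[k] + 1e-12)[bf$members[[k]][1]]))
    })
    for (k in seq_len(n - 1)) {
      expect_true(all(bf$members[[k]] %in% got_members[[k]]))
    }
  }

  d2 <- matrix(c(0, 0.1, 0.9, 0.1, 0, 0.8, 0.9, 0.8, 0), 3)
  hc2 <- complete_linkage(d2)
  expect_identical(sort(hc2$merge[1, ]), c(-2L, -1L)) # closest pair merges first
  expect_error(complete_linkage(matrix(c(0, 1, 2, 0), 2)), "symmetric")

  two <- matrix(c(0, 0.4, 0.4, 0), 2)
  hc3 <- complete_linkage(two)
  expect_equal(hc3$height, 0.4)
})

test_that("2x2 chi-square matches the closed form and standard edge cases", {
  closed <- function(a, b, c, d) {
    n <- a + b + c + d
    n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
  }
  cs <- chisq_2x2(20, 80, 10, 190)
  expect_equal(cs$statistic, closed(20, 80, 10, 190), tolerance = 1e-9)
  expect_equal(cs$statistic, 50 / 3, tolerance = 1e-9)

  # proportion-matched table: no association
  cs0 <- chisq_2x2(10, 90, 20, 180)
  expect_equal(cs0$statistic, 0, tolerance = 1e-12)
  expect_equal(cs0$p, 1)

  # transposition invariance
  cs_t <- chisq_2x2(20, 10, 80, 190)
  expect_equal(cs_t$statistic, cs$statistic, tolerance = 1e-12)

  set.seed(3)
  for (i in 1:25) {
    t4 <- rpois(4, 40) + 1
    got <- chisq_2x2(t4[1], t4[2], t4[3], t4[4])$statistic
    expect_equal(got, closed(t4[1], t4[2], t4[3], t4[4]), tolerance = 1e-9)
  }
})

test_that("cut_and_enrich finds planted enrichment and flags sparse tables", {
  set.seed(21)
  n <- 60
  ids <- sprintf("g%02d", 1:n)
  planted <- ids[1:20]
  # two coherent profile groups: background rising, planted set falling
  base <- matrix(rep(c(2, 4, 6, 8), each = n), n,
                 dimnames = list(ids, paste0("e", 1:4)))
  base[planted, ] <- matrix(rep(c(8, 6, 4, 2), each = length(planted)),
                            length(planted))
  base <- base + matrix(rnorm(n * 4, 0, 0.5), n)
  d <- correlation_distance(base, log_transform = FALSE)
  hc <- complete_linkage(d)
  enr <- cut_and_enrich(hc, 2, list(planted_set = planted,
                                    rare = ids[1:2]))
  row <- enr[enr$set == "planted_set" & enr$direction == "enriched", ]
  expect_true(any(row$p < 0.01))
  expect_true(all(enr$method[enr$set == "rare"] == "fisher"))
  expect_warning(cut_and_enrich(hc, 2, list(empty = character(0))), "empty")
})

test_that("gene-set lists expand comma-separated labels", {
  f <- new_features(c("a", "b"), "chr", "+",
                    list(rbind(c(0L, 10L)), rbind(c(20L, 30L))),
                    c("mRNA", "mRNA"),
                    gene_sets = c("s1,s2", "s2"))
  gs <- gene_set_list(f)
  expect_identical(gs$s1, "a")
  expect_setequal(gs$s2, c("a", "b"))
})
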