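#' Correlation distance between binding profiles
#'
#' d(i, j) = 1 - Pearson r between rows, computed on log10(1 + hpm) values
#' by default.  Zero-variance rows have undefined correlation; their r is
#' treated as 0 (distance 1 to everything) and the affected rows are flagged
#' in attribute `zero_variance`.
#'
#' @param m Numeric matrix (items x variables).
#' @param log_transform Apply log10(1 + x) before correlating.
#' @return Symmetric distance matrix with zero diagonal, range `[0, 2]`.
#' @export
correlation_distance <- function(m, log_transform = TRUE) {
  stopifnot(is.matrix(m), nrow(m) >= 2L)
  x <- if (log_transform) log10(1 + m) else m
  zv <- apply(x, 1L, stats::sd) == 0
  r <- suppressWarnings(stats::cor(t(x)))
  r[is.na(r)] <- 0
  d <- 1 - r
  diag(d) <- 0
  attr(d, "zero_variance") <- rownames(m)[zv] %||% which(zv)
  d
}

#' Complete-linkage hierarchical clustering
#'
#' Standard agglomerative complete linkage over a precomputed distance
#' matrix, as implemented in [stats::hclust()].
#'
#' @param d Symmetric distance matrix (zero diagonal).
#' @return An `hclust` object.
#' @export
complete_linkage <- function(d) {
  d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-12)) stop("distance matrix must be symmetric")
  stats::hclust(stats::as.dist(d), method = "complete")
}

#' Export a dendrogram as Newick
#'
#' @param hc An `hclust` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), path)
  invisible(path)
}

#' 2x2 chi-square test of association
#'
#' Pearson chi-square with 1 df, without continuity correction (the
#' classical closed form N(ad-bc)^2 / ((a+b)(c+d)(a+c)(b+d))).
#'
#' @param a,b,c,d Cell counts: `a` = in cluster & in set, `b` = in cluster &
#'   not in set, `c` = not in cluster & in set, `d` = neither.
#' @return List with `statistic` and `p` (upper-tail chi-square, 1 df).
#' @export
chisq_2x2 <- function(a, b, c, d) {
  m <- matrix(c(a, c, b, d), 2L)
  if (sum(m) == 0) return(list(statistic = NA_real_, p = NA_real_))
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  if (any(expected == 0)) return(list(statistic = 0, p = 1))
  stat <- unname(suppressWarnings(
    stats::chisq.test(m, correct = FALSE)$statistic))
  list(statistic = stat, p = stats::pchisq(stat, df = 1L, lower.tail = FALSE))
}

#' Cut a dendrogram and test clusters for gene-set enrichment
#'
#' Cuts the tree into `k` clusters and tests every (cluster, gene set) pair
#' with an uncorrected 2x2 chi-square; Fisher's exact test is substituted
#' (and flagged in the `method` column) when any expected cell is below 5.
#'
#' @param hc An `hclust` object whose labels are feature ids.
#' @param k Number of clusters (2 <= k <= number of leaves).
#' @param gene_sets Named list mapping set label to feature-id vectors.
#' @return Data.frame with one row per cluster x set: cell counts,
#'   `statistic`, `p`, `method` and `direction` (enriched/depleted).
#' @export
cut_and_enrich <- function(hc, k, gene_sets) {
  stopifnot(k >= 2L, k <= length(hc$labels))
  cl <- stats::cutree(hc, k = k)
  ids <- names(cl)
  empty <- names(gene_sets)[!vapply(gene_sets, function(s) {
    length(intersect(s, ids)) > 0
  }, logical(1))]
  if (length(empty)) {
    warning("empty gene set(s) skipped: ", paste(empty, collapse = ", "))
    gene_sets <- gene_sets[setdiff(names(gene_sets), empty)]
  }
  rows <- list()
  for (ci in sort(unique(cl))) {
    inc <- ids[cl == ci]
    for (s in names(gene_sets)) {
      set <- intersect(gene_sets[[s]], ids)
      a <- length(intersect(inc, set))
      b <- length(inc) - a
      c_ <- length(set) - a
      d <- length(ids) - a - b - c_
      m <- matrix(c(a, c_, b, d), 2L)
      expected <- outer(rowSums(m), colSums(m)) / sum(m)
      if (any(expected < 5)) {
        ft <- stats::fisher.test(m)
        stat <- NA_real_; p <- ft$p.value; method <- "fisher"
      } else {
        cs <- chisq_2x2(a, b, c_, d)
        stat <- cs$statistic; p <- cs$p; method <- "chisq"
      }
      frac_in <- if (a + b > 0) a / (a + b) else 0
      frac_bg <- length(set) / length(ids)
      rows[[length(rows) + 1L]] <- data.frame(
        cluster = ci, set = s, in_cluster_in_set = a, in_cluster_out = b,
        out_cluster_in_set = c_, out_cluster_out = d,
        statistic = stat, p = p, method = method,
        direction = if (frac_in >= frac_bg) "enriched" else "depleted",
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(cluster = integer(0), set = character(0),
                      in_cluster_in_set = integer(0), in_cluster_out = integer(0),
                      out_cluster_in_set = integer(0), out_cluster_out = integer(0),
                      statistic = numeric(0), p = numeric(0),
                      method = character(0), direction = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Gene-set list from a feature table
#'
#' Expands the comma-separated `gene_sets` column into a named list.
#'
#' @param features A `crac_features` table.
#' @return Named list mapping set label to feature ids.
#' @export
gene_set_list <- function(features) {
  sets <- strsplit(features$gene_sets, ",", fixed = TRUE)
  out <- list()
  for (i in seq_along(sets)) {
    for (s in sets[[i]]) {
      if (!nzchar(s)) next
      out[[s]] <- c(out[[s]], features$id[i])
    }
  }
  out
}
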