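#' Transcript class vocabulary
#'
#' The closed set of transcript classes used throughout the pipeline, in the
#' default attribution priority order (highest first).  `other` is the sink
#' for unknown labels so that class tables always sum to 100%.
#'
#' @return Character vector of class labels.
#' @export
crac_classes <- function() {
  c("rRNA_35S", "rRNA_5S", "tRNA", "snRNA", "snoRNA", "scR1",
    "other_polIII", "CUT", "SUT", "mRNA", "other")
}

#' Derive the transcribing polymerase for a transcript class
#'
#' 35S pre-rRNA is a Pol I product; tRNAs, 5S rRNA, scR1 and other Pol III
#' RNAs are Pol III products; everything else is Pol II.  The U6 snRNA is the
#' one exception (a Pol III snRNA) and must carry an explicit `polymerase`
#' attribute in the annotation.
#'
#' @param tx_class Character vector of class labels.
#' @param explicit Optional character vector of explicit polymerase labels
#'   (NA where absent) that override the default mapping where consistent.
#' @return Character vector of "PolI"/"PolII"/"PolIII".
#' @export
class_polymerase <- function(tx_class, explicit = NA_character_) {
  default <- ifelse(tx_class == "rRNA_35S", "PolI",
             ifelse(tx_class %in% c("tRNA", "rRNA_5S", "scR1", "other_polIII"),
                    "PolIII", "PolII"))
  explicit <- rep_len(as.character(explicit), length(default))
  pol <- ifelse(is.na(explicit), default, explicit)
  bad <- !pol %in% c("PolI", "PolII", "PolIII")
  if (any(bad)) stop("invalid polymerase label(s): ", paste(unique(pol[bad]), collapse = ", "))
  # only snRNA may legitimately deviate from the class default (U6 -> Pol III)
  dev <- !is.na(explicit) & explicit != default & tx_class != "snRNA"
  if (any(dev)) {
    stop("polymerase attribute inconsistent with transcript class for class(es): ",
         paste(unique(tx_class[dev]), collapse = ", "))
  }
  pol
}

#' Construct a feature table
#'
#' Features are stranded, possibly multi-exon annotated intervals in 0-based
#' half-open genomic coordinates, carrying a transcript class, a polymerase
#' label and optional gene-set labels.
#'
#' @param id,chrom,strand,tx_class Character vectors (recycled to length).
#' @param exons List of integer matrices with columns `start`, `end`
#'   (0-based half-open, non-overlapping, sorted in genomic order).
#' @param polymerase Optional explicit polymerase labels (NA to derive).
#' @param gene_sets Character vector of comma-separated gene-set labels
#'   ("" for none).
#' @return A `data.frame` of class `crac_features` with one row per feature
#'   and an `exons` list-column.
#' @export
new_features <- function(id, chrom, strand, exons, tx_class,
                         polymerase = NA_character_, gene_sets = "") {
  n <- length(id)
  stopifnot(length(exons) == n, !anyDuplicated(id), all(strand %in% c("+", "-")))
  exons <- lapply(exons, function(e) {
    e <- matrix(as.integer(e), ncol = 2L, dimnames = list(NULL, c("start", "end")))
    e <- e[order(e[, 1L]), , drop = FALSE]
    if (any(e[, 2L] <= e[, 1L])) stop("empty or inverted exon interval")
    if (nrow(e) > 1L && any(e[-1L, 1L] < e[-nrow(e), 2L])) {
      stop("overlapping exons within a feature")
    }
    e
  })
  tx_class <- as.character(tx_class)
  unknown <- !tx_class %in% crac_classes()
  if (any(unknown)) {
    warning("unknown transcript class(es) assigned to 'other': ",
            paste(unique(tx_class[unknown]), collapse = ", "))
    tx_class[unknown] <- "other"
  }
  df <- data.frame(
    id = as.character(id), chrom = as.character(chrom),
    strand = as.character(strand),
    start = vapply(exons, function(e) e[1L, 1L], integer(1)),
    end = vapply(exons, function(e) e[nrow(e), 2L], integer(1)),
    tx_class = tx_class,
    polymerase = class_polymerase(tx_class, polymerase),
    gene_sets = rep_len(as.character(gene_sets), n),
    n_exons = vapply(exons, nrow, integer(1)),
    stringsAsFactors = FALSE
  )
  df$exons <- exons
  class(df) <- c("crac_features", "data.frame")
  df
}

#' Load a GFF3 annotation
#'
#' Reads a GFF3 file (1-based inclusive coordinates) and assembles multi-exon
#' transcripts from `exon` lines attached to their parents.  Internal
#' coordinates are 0-based half-open.  The transcript class is taken from a
#' configurable attribute key; unknown classes are assigned to `other` with a
#' warning, and features extending beyond a chromosome end are an error.
#'
#' @param path GFF3 file.
#' @param genome A `crac_genome` used for bounds checking.
#' @param class_attr Attribute key holding the transcript class.
#' @return A `crac_features` table.
#' @export
load_annotation <- function(path, genome, class_attr = "tx_class") {
  gr <- rtracklayer::import(path, format = "gff3")
  mc <- S4Vectors::mcols(gr)
  type <- as.character(mc$type)
  is_exon <- type == "exon"
  tx <- gr[!is_exon]
  txm <- S4Vectors::mcols(tx)
  ids <- as.character(txm$ID)
  if (anyNA(ids) || anyDuplicated(ids)) stop("transcript lines need unique ID attributes")

  parent <- rep(NA_character_, sum(is_exon))
  if (any(is_exon)) {
    pl <- mc$Parent[is_exon]
    parent <- vapply(as.list(pl), function(p) if (length(p)) as.character(p)[1] else NA_character_,
                     character(1))
    if (anyNA(parent)) stop("exon line without Parent attribute")
  }
  ex <- gr[is_exon]

  exons <- vector("list", length(tx))
  for (i in seq_along(tx)) {
    sel <- which(parent == ids[i])
    if (length(sel)) {
      e <- cbind(start = GenomicRanges::start(ex)[sel] - 1L,
                 end = GenomicRanges::end(ex)[sel])
    } else {
      e <- cbind(start = GenomicRanges::start(tx)[i] - 1L,
                 end = GenomicRanges::end(tx)[i])
    }
    exons[[i]] <- e
  }

  cls <- if (class_attr %in% names(txm)) as.character(txm[[class_attr]]) else
    rep(NA_character_, length(tx))
  cls[is.na(cls)] <- "unknown"
  pol <- if ("polymerase" %in% names(txm)) as.character(txm$polymerase) else
    rep(NA_character_, length(tx))
  gsets <- if ("gene_sets" %in% names(txm)) {
    # multi-valued GFF3 attributes arrive as a CharacterList
    vapply(as.list(txm$gene_sets), function(x) {
      paste(x[!is.na(x)], collapse = ",")
    }, character(1))
  } else rep("", length(tx))

  feats <- new_features(
    id = ids,
    chrom = as.character(GenomicRanges::seqnames(tx)),
    strand = as.character(GenomicRanges::strand(tx)),
    exons = exons, tx_class = cls, polymerase = pol, gene_sets = gsets
  )
  # bounds check against the genome
  for (i in seq_len(nrow(feats))) {
    len <- genome$lengths[feats$chrom[i]]
    if (is.na(len)) stop("feature ", feats$id[i], " on unknown chromosome ", feats$chrom[i])
    if (feats$start[i] < 0L || feats$end[i] > len) {
      stop("feature ", feats$id[i], " extends beyond chromosome ", feats$chrom[i])
    }
  }
  feats
}

#' Write features as GFF3
#'
#' Inverse of [load_annotation()]: transcripts are written as `transcript`
#' lines with `ID`, class, polymerase and gene-set attributes, and multi-exon
#' features additionally as `exon` child lines.
#'
#' @param features A `crac_features` table.
#' @param path Output GFF3 path.
#' @param class_attr Attribute key for the transcript class.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(features, path, class_attr = "tx_class") {
  esc <- function(x) gsub("[;=\t]", "_", x)
  lines <- c("##gff-version 3")
  for (i in seq_len(nrow(features))) {
    attrs <- sprintf("ID=%s;%s=%s;polymerase=%s", esc(features$id[i]), class_attr,
                     features$tx_class[i], features$polymerase[i])
    if (nzchar(features$gene_sets[i])) {
      attrs <- paste0(attrs, ";gene_sets=", esc(features$gene_sets[i]))
    }
    lines <- c(lines, sprintf("%s\tcracseq\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
                              features$chrom[i], features$start[i] + 1L, features$end[i],
                              features$strand[i], attrs))
    e <- features$exons[[i]]
    if (nrow(e) > 1L) {
      for (j in seq_len(nrow(e))) {
        lines <- c(lines, sprintf("%s\tcracseq\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s",
                                  features$chrom[i], e[j, 1L] + 1L, e[j, 2L],
                                  features$strand[i], esc(features$id[i]), j,
                                  esc(features$id[i])))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Intron intervals of a feature
#'
#' @param feature One row of a `crac_features` table.
#' @return Integer matrix with columns `start`, `end` (0-based half-open,
#'   genomic order); zero rows for intronless features.
#' @export
feature_introns <- function(feature) {
  e <- feature$exons[[1L]]
  if (nrow(e) < 2L) {
    return(matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("start", "end"))))
  }
  cbind(start = e[-nrow(e), 2L], end = e[-1L, 1L])
}

#' Map template coordinates to genomic coordinates
#'
#' The template of a feature is its transcript-oriented sequence, either the
#' unspliced precursor (the full genomic span) or the mature spliced form.
#' Returns, for every template position 0..T-1, the 0-based genomic
#' coordinate of that base.
#'
#' @param feature One row of a `crac_features` table.
#' @param template `"precursor"` or `"mature"`.
#' @return Integer vector of genomic coordinates.
#' @export
template_map <- function(feature, template = c("precursor", "mature")) {
  template <- match.arg(template)
  if (template == "precursor") {
    g <- seq.int(feature$start, feature$end - 1L)
  } else {
    e <- feature$exons[[1L]]
    g <- unlist(lapply(seq_len(nrow(e)), function(j) seq.int(e[j, 1L], e[j, 2L] - 1L)),
                use.names = FALSE)
  }
  if (feature$strand == "-") g <- rev(g)
  g
}

#' Transcript-oriented template sequence of a feature
#'
#' @inheritParams template_map
#' @param genome A `crac_genome`.
#' @return Character scalar (5'->3' in transcript orientation).
#' @export
feature_sequence <- function(genome, feature, template = c("precursor", "mature")) {
  template <- match.arg(template)
  if (template == "precursor") {
    s <- genome_seq(genome, feature$chrom, feature$start, feature$end)
  } else {
    e <- feature$exons[[1L]]
    s <- paste(vapply(seq_len(nrow(e)), function(j) {
      genome_seq(genome, feature$chrom, e[j, 1L], e[j, 2L])
    }, character(1)), collapse = "")
  }
  if (feature$strand == "-") s <- revcomp(s)
  s
}
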