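Package: cracseq
Title: Downstream Analysis of CRAC Protein-RNA Crosslinking Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computational analysis of CRAC (UV crosslinking and analysis of
    cDNA) experiments on RNA-degradation machinery such as the yeast exosome:
    duplicate collapsing and adapter trimming, a desk-scale seed-and-extend
    aligner with SAM import/export, non-templated 3' oligo(A) tail calling,
    microdeletion-based crosslink-site mapping, transcript-class attribution
    with hits-per-million normalization, per-base coverage and metagene
    profiling, splice-junction statistics, and binding-profile clustering
    with gene-set enrichment.  Includes a synthetic CRAC read simulator with
    ground-truth manifests for validating every stage of the pipeline.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    ape,
    Rcpp,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
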