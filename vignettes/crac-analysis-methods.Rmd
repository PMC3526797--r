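---
title: "Methods: downstream analysis of CRAC crosslinking data"
author: "cracseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: downstream analysis of CRAC crosslinking data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

CRAC (UV crosslinking and analysis of cDNA) recovers short RNA fragments
bound in vivo by a tagged protein.  Three sequence-level signatures carry
the biology, and everything in this package is organized around recovering
them:

* **Non-templated 3' oligo(A) tails** (two or more terminal adenosines
  absent from the reference) mark RNAs that the TRAMP poly(A) polymerase
  has flagged for degradation by the nuclear exosome.  The fraction of
  A-tailed reads in a dataset is a readout of how strongly the purified
  protein engages surveillance substrates.
* **Microdeletions** of 1-2 nt are introduced by reverse transcriptase at
  the crosslinked nucleotide; per-base deletion density therefore maps the
  protein's binding site at near-nucleotide resolution, more precisely
  than read coverage.
* **Class composition and positional profiles** -- which transcript
  classes (rRNA, tRNA, snoRNA, snRNA, mRNA, CUT/SUT, other Pol III RNAs)
  a protein binds, where along each RNA it sits, and whether it prefers
  unspliced precursors (intron-exon junctions) over mature RNAs
  (exon-exon junctions).

All tracks and tables are normalized to **hits per million mapped reads
(hpm)**: each counted read contributes `1e6 / N` where `N` is the number
of counted (unique, non-multi-mapping) reads in the dataset, so datasets
of different depth are directly comparable.  Per-RNA hpm columns sum to
exactly `1e6`, with unassigned reads kept in an explicit `intergenic` row.

# Pipeline

Reads are processed as: duplicate collapse (exact sequence identity; the
multiplicity is kept as a `count` column) -> 3' adapter trimming (longest
read suffix matching an adapter prefix with at least 5 nt overlap and at
most one mismatch; reads shorter than 15 nt are discarded) -> alignment ->
junction lifting -> tail and deletion calling -> class attribution ->
profiles, splicing statistics and clustering.

## Alignment

The built-in aligner is a desk-scale seed-and-extend mapper for 20-50 nt
CRAC reads: the read's 5'-most 12-mer is matched exactly against both
strands of the genome and against exon-exon junction entries, and each
seed is extended 3'-ward by a banded dynamic program that allows
mismatches (-2), 1-3 nt reference deletions (-3 per event, at most 6 nt
total) and matches (+1).  Trailing bases that do not improve the score
become a 3' soft clip, which is what lets non-templated tails survive
alignment.  Score ties between a longer and a shorter extension keep the
shorter one (larger clip): only strictly score-improving segments are
aligned, and any exactly templated clip prefix is re-absorbed later during
tail calling, so the final alignment is identical either way except that
chance part-matching segments (sequencing adapter read-through, tails over
A-rich context) are not frozen into the alignment.  Reads with more than
one distinct best locus are flagged multi-mapped and excluded from
counting; ties are otherwise resolved to the lowest (reference,
coordinate).  Junction-entry hits only count as loci when the alignment
actually crosses the splice boundary -- a one-sided hit is the same
genomic locus as the direct genomic alignment and must not create a
spurious multi-mapping flag.

The aligner is validated against an exhaustive, unseeded oracle
(`oracle_align_scores()`) that enumerates every start position on both
strands, every single-deletion placement (1-3 nt at every read position)
and every 3' clip under the same scoring scheme.  On error-free simulated
reads the seeded aligner attains the oracle's optimal score for every
read; the package's acceptance checks require at least 99%.  A read whose
first 12 nt contain a deletion or substitution has no exact seed and is
reported unmapped -- the stated and deliberate limitation of seeding.

External alignments can be imported from SAM (`read_sam()`), which is
also the export format; `=`/`X` are normalized to `M`, and hard-clipped or
padded records are rejected.

## Tail calling

`call_tails()` re-extends every 3' soft clip against the downstream
reference in transcript orientation: any clip prefix that matches is
templated and is moved back into the aligned span.  If an adapter is
supplied, an exact terminal match between a clip suffix and an adapter
prefix is then stripped -- this handles adapter read-through of 1-4 nt,
which is too short for overlap-based trimming to see.  What remains is
the candidate tail; a read is A-tailed when the tail has at least `min_A
= 2` nt, at least `min_A` adenosines, and passes the purity threshold
(default 1, i.e. the strict all-A rule; `purity` can be relaxed to accept
majority-A tails).

Two consequences of the strict, extension-first definition are worth
stating.  First, the call is idempotent and deterministic.  Second, it is
conservative: a genomic A immediately downstream of the binding site
absorbs the first tail adenosine(s) as "templated", so tails over A-rich
context are undercounted.  On the default simulated datasets about 15% of
true tails are lost this way; `scripts/acceptance.R` measures this as
`atail_recovery_pct` rather than hiding it.  Under unambiguous conditions
(a genome free of A on the transcript strand, no sequencing errors, no
deletions) tail calling is exact -- sensitivity and specificity are both
1.0 on 10,000 reads, and the acceptance suite holds it to that.

## Attribution and class tables

Each counted alignment is attributed to exactly one feature.  Among
same-strand features whose flank-extended span (default +/-50 nt, so that
5'/3'-extended precursor reads attribute to their gene) overlaps the
alignment, the highest-priority class wins; the default priority is
rRNA_35S > rRNA_5S > tRNA > snRNA > snoRNA > scR1 > other Pol III > CUT >
SUT > mRNA > other, which keeps a snoRNA nested in an mRNA intron from
being swallowed by its host.  Ties within a class go to the larger
overlap, then the lexicographically smaller id.  No overlap means
`intergenic`.  The attribution's `region` records exon / intron /
5'-flank / 3'-flank / junction-EE.

Class distributions, polymerase partitions (Pol I = 35S; Pol III = tRNA,
5S, scR1, other Pol III and the U6 snRNA via an explicit `polymerase`
attribute; Pol II = the rest) and A-tail frequency tables can be computed
per unique read (default) or weighted by duplicate multiplicity
(`weight = "count"`).  The count weighting matters when comparing against
sampling proportions: short, highly covered features (tRNAs) lose many
more reads to duplicate collapse than long mRNAs, so unique-read
fractions systematically under-represent them.

## Profiles and splicing statistics

Hit tracks add the hpm weight to every M-covered base (deletion and
splice gaps are not covered); deletion tracks add it to every deleted
base, indexing the crosslinked nucleotide itself.  Tracks can be filtered
to A-tailed reads, and the A-tailed track is pointwise bounded by the
total.  The pre-mRNA metagene anchors every spliced gene at the 3' splice
site of its first (transcript-order) intron, orders rows by intron length
and keeps raw hpm (no per-gene normalization) so that expression-driven
coverage differences stay visible; a row-normalized export is available.
tRNA profiles are anchored at the mature 5' end, ranked by precursor
length (intron included) and retain +/-50 nt flanks so leader/trailer
reads from pre-tRNAs are visible.

Junction statistics count a read toward a boundary only when the
alignment covers it with at least `min_overhang` aligned nt on each side;
exon-exon (EE) counts require a junction-library alignment, intron-exon
(IE) counts a contiguous genomic M segment across the boundary.  The
default overhang of 1 nt is the most permissive reading; because 1-4 nt
of untrimmable adapter read-through can coincidentally match the genome
just across a boundary, the analysis scripts and acceptance checks use an
overhang of 5 nt (a chance crossing cannot be built from a <= 4 nt
remnant), and a sensitivity table over overhangs {1, 3, 5} is emitted.
Ratios (IE/EE, introns/total-mRNA, 3'SS/5'SS window sums) are computed
per replicate and averaged; the SE is the sample SD over sqrt(r), or a
seeded 1,000-resample bootstrap over genes when only one replicate
exists.  Intron-mapped counts include any read with an aligned base in an
intron, accepting that excised-intron fragments are indistinguishable
from pre-mRNA reads in short-read data.

## Clustering and enrichment

Binding profiles are compared by correlation distance, `d = 1 - r` on
`log10(1 + hpm)` values (the log compresses the heat-map dynamic range so
a handful of saturated RNAs does not dominate `r`); zero-variance rows
get distance 1 to everything and are flagged.  Agglomeration is standard
complete linkage (`stats::hclust`), validated in the test suite against a
stepwise brute-force oracle that recomputes the maximal inter-cluster
distance at every merge.  Both axes are clustered: experiments (where
replicates of a condition are expected to merge first -- the package's
reproducibility check) and mRNAs.  Cluster membership at a user-chosen
`k` (no automatic cut is attempted) is tested per gene set with an
uncorrected 2x2 chi-square (1 df); Fisher's exact test is substituted and
flagged when any expected cell is below 5.  Benjamini-Hochberg correction
is available but off by default, matching the convention of reporting raw
chi-square p-values for a handful of planned sets.

# The synthetic data generator

Real CRAC datasets for this class of experiment live in sequence
archives and are not redistributable inside a package, so the generator
is a first-class module that emulates their statistical structure and
carries a complete ground-truth manifest (per read: source feature,
template, coordinates, introduced deletions, appended tail, errors).

`forge_genome()` builds a random-sequence chromosome (~34 kb by default)
with 44 non-overlapping features on both strands: a 2.5 kb 35S rRNA unit
standing in for the Pol I transcription unit with its 5' spacer region,
one 5S (121 nt), one scR1 (520 nt), U6 as a Pol III snRNA (112 nt),
spliced mRNAs with a bimodal intron-length mix (~400 nt "long" introns
labelled `ribosomal_protein`, ~100 nt "short" introns; both labelled
`intron_containing`), intronless mRNAs (half labelled
`ribosome_synthesis_factor`), intronless and intron-containing tRNAs
(introns 14-30 nt after the anticodon-arm position), snoRNAs, snRNAs,
CUTs and SUTs.  Feature sequence is whatever the random genome provides
-- every analysis here depends only on coordinates, not motifs.

`simulate_reads()` draws, per read: a feature (class weights define each
class's total sampling mass; per-feature multipliers redistribute mass
within a class only, so class totals are exactly the configured weights);
a template (unspliced precursor with probability `pre_mature_ratio`;
tRNA precursors additionally extend 15 nt beyond the mature ends to
emulate leaders and trailers); a start position from a mixture of a
Gaussian peak over the crosslink site (70% by default, SD 10 nt) and a
uniform background; then applies substitution errors (0.2%/nt), a 1-2 nt
deletion at a covered crosslink site with probability `delete_prob`
(lengths 1:2 at 0.8:0.2), a geometric >= 2 nt oligo(A) tail with the
class's `a_tail_prob`, and adapter read-through up to the 50 nt cycle
length.  One deterministic crosslink site per feature sits at 45% of the
precursor length unless overridden.  Reads are sense-strand; an
antisense contamination knob exists and defaults to 0.  Everything is
reproducible from the single config seed, byte-identically.

The default 3' adapter is the miRCat-style CRAC adapter
`TCGTATGCCGTCTTCTGCTTG`.  Its prefix contains no A and no shift-1
self-similarity, which matters: one-mismatch overlap trimming against an
adapter with `AA` in its first five bases can delete a genuine
`...NN + AA` tail, making exact tail recovery impossible.

`crac_condition_presets()` packages five parameter sets emulating the
qualitative signatures of exosome-subunit datasets; their headline
numbers (total A-tail probabilities of 0.6%/0.4%/19.5%/10%/40.3%; Pol III
class mass of ~5%, ~40% for the exonuclease-dead mutant, 18.2% for the
poly(A) polymerase; precursor fractions up to 0.61, chosen so the
nuclear-exonuclease condition shows the ~2-fold IE/EE excess such
datasets display) are taken from the published characterizations of
those proteins.  Per-condition log-normal feature multipliers
(`sdlog = 0.8`), shared across replicates, give each condition a
distinctive per-RNA fingerprint on top of the class weights.

**What the simulator does not model** -- and hence what passing tests do
not demonstrate about real data: PCR amplification bias (duplicates arise
only from genuine sampling collisions), base-quality structure, ligation
sequence preferences, multi-site crosslinking per RNA, non-A tails
(CUCU-type), antisense transcription, paralogous gene families (the
random genome has essentially no repeats, so multi-mapping is rare by
construction), and chimeric/circularized reads.  Results on real data
additionally depend on the external aligner when SAM import is used.

# Numerical and design choices

* Internal coordinates are 0-based half-open; GFF3 i/o is 1-based
  inclusive; bedGraph is 0-based half-open.  All "5' end" / "3'SS" logic
  is transcript-oriented; minus-strand features store exons in genomic
  order.
* The transcript-class vocabulary is closed, with `other` as the sink, so
  class tables always partition 100%.
* Alignment scores (match +1, mismatch -2, deletion event -3) are chosen
  so that one deletion (-3) beats two mismatches (-4) but a lone terminal
  mismatch is clipped rather than absorbed.
* `ratio_with_se()` excludes replicates with zero denominators with a
  warning; bootstrap SEs are seeded.
* Deletion density indexes the deleted reference base (not the read 5'
  end); multi-nt deletions contribute one event per deleted base, with a
  per-read mode available through `extract_deletions()` consumers.
* Multi-intron genes anchor the metagene at their first
  (transcript-order) intron.
* Problem sizes: unit tests run on 0.5-20 k-read simulations over the
  ~34 kb forged genome; the end-to-end validation uses 10 k reads for
  tail exactness, 80 k for crosslink recovery, 50 k for mixture recovery,
  five 50 k-read points for the IE/EE dose curve, and 4 conditions x 2
  replicates x 50 k reads for clustering cohesion; the analysis scripts
  use 20 k reads per replicate and `scripts/acceptance.R` 30 k.  These
  sizes put every statistic well past its convergence scale (binomial SDs
  below 0.25 percentage points) while keeping a full run in minutes on
  one core.

# Known limitations

* The seed requires the first 12 nt to be error- and deletion-free;
  crosslink sites very close to the read 5' end are invisible.  Real
  datasets should be aligned with a production aligner and imported as
  SAM when this matters.
* Tail undercounting in A-rich downstream context is inherent to the
  strict templated-extension rule; the bias is measured on simulation
  (~15% of tails at default settings) and should be kept in mind when
  comparing absolute A-tail percentages between genomic contexts.
* 1-2 nt junction overhangs cannot be distinguished from chance matches
  of adapter read-through; use overhang >= 5 for contamination-robust
  junction statistics (the default of 1 reproduces the most permissive
  literal counting rule).
* Fractional (multi-feature) attribution is not implemented; the
  single-label priority rule is a deliberate partition so that class
  percentages are additive.
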