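---
title: "Detecting and characterising circRNAs from paired-end reads"
author: "circjunct"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and characterising circRNAs from paired-end reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circjunct)
```

## The problem

Circular RNAs (circRNAs) arise when a downstream splice donor is joined to
an upstream splice acceptor of the same transcript — a *back-splice* — so
the molecule has no free ends and no poly(A) tail. In an RNA-seq library a
read crossing the back-splice maps in *reversed* genomic order: along the
genome the two exon termini appear as `a–b ... c–d`, but in the circle they
read `c–d–a–b`, so the read's 5' part lands genomically *downstream* of its
3' part. That reversed-order signature is the only direct sequence evidence
a circRNA leaves, and it is what this package detects, counts and
characterises, at the depths typical of single-cell and low-input
libraries.

## The junction caller

The caller mirrors a split-anchor workflow:

1. **QC and trimming** (`qc_pairs()`): adaptors and artificial
   poly(A)/poly(T) tails (runs of 24 or more) are trimmed; reads are
   dropped when at least 50% of bases have Phred quality 5 or less, more
   than 10% of bases are undetermined, A+T content exceeds 80%, or the
   trimmed read is shorter than 60 bp. A pair is dropped when either mate
   fails. The 50% rule is inclusive (the printed threshold itself drops);
   the N and AT rules are exclusive, following their printed "more than"
   phrasing. The low-quality and undetermined rules are applied as two
   independent drop rules.
2. **Anchor extraction** (`extract_anchor_pairs()`): the first and last
   25 bp of every read at least 60 bp long become its head/tail anchor
   pair; 60 bp guarantees a gap of at least 10 bp between anchors.
3. **Anchor placement** (`align_anchor()` / `ingest_sam()`): anchors are
   placed ungapped on both strands (the library is random-primed, hence
   unstranded). The built-in matcher (backed by Biostrings exact/mismatch
   matching) serves desk-scale genomes; alignments from an external
   aligner can be ingested as SAM instead. Anchors with more than
   `max_hits` (default 10) placements are discarded as multimapping.
4. **Candidate pairing** (`pair_candidates()`): both anchors on one
   chromosome, one strand, in reversed order (on a plus-strand placement
   the tail anchor sits upstream of the head anchor), within `max_span`.
   The span default is 100 kb; the source workflow states both 100 kb and
   200 kb in different places, and we default to the stricter bound,
   exposed as a parameter.
5. **Boundary resolution** (`resolve_junction()`): a candidate read must be
   explained by a *single annotated transcript*: an exon block `i..j`
   (single-exon circles allowed) such that the read splits into a prefix
   ending exactly at the donor boundary of exon `j` and a suffix starting
   exactly at the acceptor boundary of exon `i`, with at most
   `max_mismatch` (default 2) substitutions over the whole read. Requiring
   annotated boundaries of one transcript eliminates trans-splicing
   chimeras and exon tandems; it also means unannotated splice sites are
   out of scope by design. Reads explained by more than one distinct
   junction are dropped rather than fractionally assigned, because support
   is counted in whole reads.
6. **Mate consistency** (`mate_consistent()`): the mate of a junction read
   must come from inside the circle, so it passes only if it is unmapped
   (non-informative) or placed within `[acceptor_start, donor_end]`. The
   filter can be disabled (`mate_filter = FALSE`) since the original
   analysis reports this check as an inspection rather than a hard rule.
7. **Aggregation** (`aggregate_calls()`): identical junctions are grouped;
   a fragment counts once even if both mates span the junction; calls need
   at least `min_support` junction reads (default 2). Per-sample support is
   recorded so several cells can be merged into one calling run.

Coordinates are 0-based half-open internally; GTF, SAM and the
`chrom:start-end` report labels convert at I/O boundaries only.

## The synthetic-data generator

Real single-cell libraries for this task are hundreds of millions of
reads; the generator (`simulate_dataset()`) reproduces the *structure* of
that data at desk scale so every stage is testable against a known truth:

* a toy genome (two chromosomes) with 20 non-overlapping multi-exon genes
  separated by at least 10 kb, on both strands, one transcript each, with
  4–8 exons of 150–400 bp and introns of 0.5–8 kb;
* 8 planted circRNAs over internal exon blocks, about 10% of them
  single-exon (circles in this data are mostly multi-exon, with roughly
  one in ten formed by a single exon); among candidate blocks the one
  with the longest flanking introns is preferred, reflecting the observed
  association between long flanking introns and circularisation;
* 5 junction-spanning fragments per circle (100-bp FR paired-end reads,
  fragment length 250 ± 30 bp, random sequenced strand), the mate placed
  within the circle;
* Poisson linear coverage of every transcript, trans-splicing decoy
  fragments joining exon boundaries of two different genes, ERCC spike-in
  fragments proportional to input molecules, and QC-fail pairs violating
  exactly one QC rule each;
* a truth table of every planted feature.

The junction split point is drawn uniformly while keeping at least
`junction_overhang_min` bases on each side of the back-splice. The default
of 25 bp equals the anchor length, so every planted junction read is
recoverable and planted recall can be asserted to be exactly 1. Setting it
to 1 bp reproduces the physical minimum, in which case the truth table's
`planted` and `recoverable` counts differ and only the latter bounds the
caller — this makes the 25-bp-anchor detectability limit explicit rather
than hiding it in flaky tests.

What the generator does *not* emulate: indels and quality-dependent error
models (substitutions occur at a flat rate), PCR duplicates, expression
heterogeneity across cells, incomplete annotation, and repeat-rich genome
structure. Passing tests therefore demonstrate algorithmic correctness on
clean data, not calling performance on real libraries; headline counts
from deposited datasets are not reproducible at this scale and are not
asserted anywhere.

## Quantification

* `fpkm()` implements the plain fragments-per-kilobase-per-million formula
  over exon-model lengths. Isoform-deconvolving estimators produce
  different values on multi-isoform genes; plain FPKM is the transparent,
  testable contract here and the deviation is intentional.
* `junction_rpm()` normalises junction-read counts per million mapped
  paired-end fragments — circRNA evidence is only the junction-spanning
  reads, so this is the natural depth normalisation.
* `host_normalized()` divides junction reads by host-gene FPKM (plus a
  pseudocount) for cross-gene comparisons.
* `ercc_calibrate()` regresses log10(known molecules) on log10(FPKM) over
  detected spike-ins (at least 8 required) and `absolute_copies()` inverts
  the fit. The deduction formula is not prescribed by the source analysis;
  log–log least squares matches the observed linearity of spike-ins, and
  leaving the slope free absorbs capture-efficiency nonlinearity. For
  circRNAs the expression fed into the calibration uses junction reads
  with the circle length as feature length — a documented bridge, since
  only junction reads are counted but molecule numbers are reported.
* `polyA_minus_genes()` applies the poly(A)- detection rule: at least
  2-fold enrichment in rRNA-depleted versus oligo(dT)-enriched libraries
  (Student t-test on log2(FPKM+1), p below 0.05), mean FPKM above 1 in the
  double-depleted libraries, and gene length at least 300 bp. The fold
  threshold is inclusive ("at least a twofold"); the length filter
  excludes genes under 300 bp.
* `classify_maternal_zygotic()` classifies maternal genes (at least 4-fold
  enrichment in oocytes, p below 0.05) and zygotic genes (4-fold in
  two-cell embryos), and validates zygotic genes by 4-fold down-regulation
  under transcription inhibition. Fold changes use mean CPM with a
  pseudocount of 1 (zero handling is otherwise unspecified). The two-group
  test is pluggable; the default is a per-gene t-test on log2(CPM+1)
  rather than a dispersion-modelled count test, so gene lists on real data
  will differ from an exact negative-binomial analysis even though the
  classification rule itself is identical.

## Formation features

`flanking_introns()` identifies the intron immediately 5' (transcript
order) of the circle's acceptor exon and immediately 3' of its donor exon
— the two introns removed by the back-splice — and the lengths of all
other introns of the transcript; flanks are absent when the circle reaches
the transcript's first or last exon.

`find_rc_pairs()` searches for reverse-complementary (RC) sequence between
the two flanking introns, the hypothesised base-pairing that brings splice
sites together. Scoring follows the blastn parameterisation: word size 11,
match +2, mismatch −3, gap open 5, gap extend 2 (a gap of length L costs
5 + 2L), with the downstream intron as query and the reverse complement of
the upstream intron as subject. Alignments of aligned length at least 25
("longer than 25" read inclusively, an off-by-one the source leaves
unstated) containing a perfect 11-mer core are reported; the best
alignment is taken, its footprint masked, and the search repeated, giving
non-overlapping pairs. Up to a budget of 4.5 million matrix cells (about
2 kb × 2 kb) the greedy search runs exact full-matrix affine-gap local
alignment (a Smith–Waterman in compiled code); larger intron pairs are
searched exactly the same way but inside windows (±500 bp) around each
cluster of shared 11-mer words, the blastn-style compromise that keeps the
search linear in practice. On instances within the exact budget the finder
provably reports the same alignments as an independent full-DP oracle, and
the test suite asserts this equivalence.

`classify_rc()` groups circRNAs into `NonRC` (no qualifying pair),
`RC-repeats` (a pair segment overlaps an annotated repeat element by at
least 1 bp — the minimal overlap rule, configurable) and `RC-Nonrepeats`.
`rc_distance()` sums each pair's distances to the two splice sites and
reports the nearest pair; `repeat_density()` counts overlapping repeat
intervals per kb of intron.

Splice-site motif *strength* scoring is deliberately excluded: no scoring
scheme is specified for it in the source analysis, so any choice would be
a guess presented as a reproduction.

## Numerical and design choices

* **Tie-breaks / ambiguity**: anchors over the multimap cap are discarded;
  reads explained by two distinct junctions are dropped; in the RC search,
  ties between equal-scoring alignments may be reported in either order
  (comparisons in tests are order-insensitive).
* **Degenerate inputs**: trimming may empty a read (then dropped as
  short); `N` bases never match in any aligner; empty call sets write
  header-only BED files; calibration aborts below 8 detected spike-ins.
* **Determinism**: every stochastic step derives from a single integer
  seed; simulator runs are byte-identical for a fixed config, and calling
  is invariant to read order.
* **Problem sizes**: the bundled checks run on 20-gene toy genomes
  (hundreds of kb), about 10^4 read pairs, 100 oracle genomes of 8–50 kb,
  50 RC instances up to 2 kb, and expression matrices of about 10^3 genes
  — sizes chosen so the full suite exercises every code path in minutes
  on one core while remaining statistically meaningful.

## Known limitations

* Junctions are restricted to annotated exon boundaries of a single
  transcript; intronic, intergenic and unannotated-splice-site circles are
  invisible by design.
* The built-in anchor matcher is for toy genomes; real genomes should go
  through an external aligner and `ingest_sam()`.
* Plain FPKM and the t-test default understate the sophistication of
  isoform-aware estimators and count-based tests on real data.
* Absolute circRNA copy numbers inherit the junction-reads/circle-length
  bridge; treat them as order-of-magnitude estimates.
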