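---
title: "Methods: consensus DGE and splice-junction AS calling for paired salt-stress libraries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus DGE and splice-junction AS calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saltdge)
```

# The analysis problem

`saltdge` re-implements a digital gene expression (DGE) comparison of two
sister species under salt stress, in the design that was common for early
Illumina transcriptome studies: one control and one salt-stressed cDNA
library per species — four libraries, **no biological replicates**.  With a
single library per condition, replicate-based dispersion estimation is
unavailable; the workflow instead relies on

1. exact count tests that condition on the library totals,
2. a *consensus* rule — a gene is differentially expressed only if **every**
   configured metric calls it at FDR < 0.05 — plus an effect-size criterion
   (|log2 FPKM ratio| > 1) and an expression floor (FPKM ≥ 1 in at least one
   library), and
3. orthogonal confirmation (qPCR fold changes, Pearson r).

Alternative splicing is surveyed without spliced alignment: a database of
candidate splice junctions is built from the annotation, each junction is
represented by its flanking exonic sequence, and a junction is *validated*
in a library when at least two reads align to that flank sequence
gaplessly, with at most one mismatch, spanning the boundary.  Validated
junction geometry is then read out as six event types: skipped exons (SE),
retained introns (RI), alternative 5'/3' splice sites (A5SS/A3SS) and
alternative first/last exons (AFE/ALE).

Because the original study's inputs (tens of millions of reads, a full
poplar annotation) are not desk-scale, the package ships a synthetic-data
generator that emulates the statistical structure the analysis assumes and
records the planted truth, so every stage can be scored end to end.

# Pipeline stages and their models

## Read quality control

Four rules, applied in order, each with a removal count in the QC report:
exact duplicate sequences are collapsed to their first occurrence;
low-complexity reads are removed (concretised as a single base making up
≥ 80% of the read — the rule is named but not defined in the protocols this
emulates, so the package states its definition explicitly); reads with
more than 8 unknown bases are removed; and reads with more than half of
their bases at Phred quality ≤ 5 are removed.  Qualities are Sanger
Phred+33.  Input = kept + removed at every stage, and the suite asserts
this conservation.

## Matching and quantification

Reads are matched **gaplessly** to transcript (not genome) sequences with
at most one mismatch, on both strands, and every qualifying offset is
reported.  The engine splits each read into two pieces, finds exact piece
hits with an Aho–Corasick dictionary scan over the concatenated
transcripts, and verifies candidates by direct Hamming count — by the
pigeonhole principle this is exactly equivalent to scanning every offset,
and the test suite asserts equality with a brute-force scan on hundreds of
random instances.  An `N` matches only itself, so it consumes a mismatch.

Reads hitting transcripts of two or more distinct genes are discarded;
reads hitting a single gene count once.  Expression is FPKM,
`C * 1e9 / (L * N)`, with `N` the library's uniquely mapped fragments;
transcripts below FPKM 1 in both libraries of a species are filtered out.
Report percentages are rounded half away from zero to one decimal, which
is what the published summary tables print.

## The consensus DEG caller

Two exact metrics are built in, behind a pluggable interface that accepts
any `f(x, y, N1, N2) -> p`:

* **Poisson-ratio (conditional) test.**  Given `x` tags among `N1`, the
  count `y` among `N2` follows
  `P(Y = y | x) = r^y (x+y)! / (x! y! (1+r)^(x+y+1))`, `r = N2/N1` — a
  negative binomial with size `x+1` and success probability `N1/(N1+N2)`.
  The two-sided p doubles the smaller (point-inclusive) tail, capped at 1.
  Note that this conditional construction is *not exactly* symmetric under
  exchanging the libraries (the conditioning variable changes); the tails
  agree on the log scale and the suite tests that near-symmetry, with
  exact symmetry in the equal-library case.
* **Fisher's exact test** on `[[x, N1-x], [y, N2-y]]`.

The consensus is intersection semantics: *up* requires `log2 ratio > 1`,
FPKM ≥ 1 somewhere, and **every** metric's BH-adjusted p below 0.05.
Adding a metric can therefore only shrink the called set (tested as a
property).  FDR is Benjamini–Hochberg, the standard step-up procedure.

Zero FPKM in a ratio denominator (or numerator) is floored at a
configurable pseudo-FPKM, default **0.001**.  The default reproduces the
published worked example of a (0.00 → 15.30) pair printing a log2 ratio
of 13.90, but remains a parameter rather than an asserted calibration.

DEGs from the two species are classified into the eight cross-species
clusters (exclusive up/down per species, co-up, co-down, two opposing
patterns).  The clusters partition the DEG union, so per-species totals,
the common count and the union all reconstruct from the eight sizes —
`cluster_totals()` is that arithmetic, and the bundled worked example
checks it against published counts.

## Enrichment

PAGE computes `Z = (Sm − mu) * sqrt(m) / delta` per gene set, with the
background being **all transcripts passing the expression filter** (PAGE
is a whole-distribution method; published tables report sets whose means
sit below the DEG threshold), p from the standard normal and BH FDR.
Sets with fewer than 10 scored members are skipped, matching the smallest
set size the emulated reports print.  The suite checks null calibration
(mean and variance of Z over 1000 random sets) and the complement
identity `m*Sm + (Nb−m)*S̄c = Nb*mu`.

SEA is the upper-tail hypergeometric on DEG membership with Bonferroni
correction over the tested terms (significant at corrected p < 0.05),
verified against full enumeration on small universes.

## qPCR cross-validation

`ddct()` implements 2^−ΔΔCt with a reference gene per replicate and a
calibrator sample; `validate_correlation()` is the Pearson r between qPCR
and RNA-seq log2 fold changes.  The generator's synthetic assay drops the
target's Ct by the planted log2 fold change (one cycle per doubling) with
0.2-cycle replicate noise.

## Splice-junction analysis

* **Junction database.** All ordered exon pairs `(ei, ej), i < j` of each
  gene — `n(n−1)/2` junctions per gene — merged with a novel-junction file
  (plain TSV or TopHat-style BED12), deduplicated on
  (contig, donor, acceptor, strand) with annotated origin winning.
* **Flanks.** Up to 65 exonic bases each side of the boundary, truncated
  at the containing exon or contig; reverse-complementation for
  minus-strand genes happens only at output.
* **Validation.** A read supports a junction if it aligns to the flank
  with ≤ 1 mismatch and overlaps the boundary by ≥ 8 bases on each side
  (`min_anchor`); ≥ 2 distinct reads validate it.  The anchor default is
  a package decision: the emulated protocol states read length and the
  mismatch cap but no anchor rule, and without one any read merely ending
  at the boundary would "span" it.
* **Retained introns** use two retention pseudo-junctions per intron
  (contiguous genomic sequence across each exon/intron boundary); an RI
  is called only when *both* boundaries have ≥ 2 anchored reads.
* **Classification.**  Junction pairs sharing an acceptor with donors in
  the same exon are alternative splice-site events (A5SS on plus-strand
  genes at the genomic-left side; labels swap with strand); pairs whose
  donors lie in *different* exons, neither of which receives the acceptor
  of any **validated** junction, are AFE/ALE.  Junctions not consumed by
  a pair event and whose span contains ≥ 1 annotated exon are SE events
  (one event per junction, carrying its skipped-exon set).  Pair events
  take precedence over SE so a junction pair is never double counted.

  Restricting the AFE/ALE disqualifier to *validated* junctions (rather
  than all annotated exon pairs) is deliberate: with a single-isoform
  annotation every non-first exon is the acceptor of some annotated pair,
  which would make alternative first exons undetectable by construction.
  Observed connectivity is the evidence that an exon is internal.
* **Aggregation.**  Per-library totals are column sums over types; the
  cross-library `Total` is a union by event identity
  (type, gene, defining coordinates) — inferred from published tables
  whose total column is smaller than the column sums.  Locus reports
  count distinct genes, with cross-species and salt-specific overlaps.

# The synthetic-data generator

`sim_config()` defaults define the study conditions used by the recovery
checks: 500 genes (3–6 exons of 120–300 bp, introns 80–200 bp, random
strand, non-overlapping on a handful of contigs), log-normal relative
abundance (log-mean `log 20`, log-sd 1), 40,000 fragments per library,
75-bp single-end reads (the analysis consumes fragment counts, not pair
geometry, so paired-end is emulated at the count level), negative
binomial counts with dispersion 0.02 (single-condition DGE libraries are
near-Poisson; the mild overdispersion keeps the exact tests honest
without swamping them), planted |log2 effect| ≥ 2 drawn as
`2 + U(0, 0.5)`, and a 50-fragment control-library floor for planted
genes so planted effects are estimable.  Eight DE class fractions default
to 3% per exclusive class, 2% per co-regulated class and 0.5% per
opposing class.  Expected counts are normalised by baseline mass only, so
a planted gene's expected log2 ratio is exactly its planted effect and
the planted mass drifts the realised library size slightly, as in a real
run.

AS events are planted at 4–5% per type, at most one event per gene and
never in a DE gene (keeping the two ground truths orthogonal).  Every
defining junction of a planted event receives ≥ 2 spanning reads with
≥ 8-base anchors in each target library, sampled at distinct offsets so
deduplication cannot erase them.  Planted SE events also emit reads for
the two *inclusion* junctions: a skipped exon is only interpretable as
skipped when the inclusion isoform is observed, otherwise a low-coverage
gene reads as an alternative terminal exon.  AFE/ALE genes express the
isoform that omits the alternative exon, so the contradicting
consecutive junction stays unsupported.  Alternative 5'/3' sites are
planted 12 bp inside the exon and exported through the novel-junction
file, exercising the merge path.

Contaminants are injected at configured rates (1% exact duplicates, 0.5%
N-rich, 0.5% low-quality) to exercise QC.

**What the generator does not emulate:** sequencing errors beyond the
QC-relevant contaminants (so matching operates at 0–1 true mismatches),
insert-size geometry, multi-isoform annotations, positional coverage
bias, and cross-gene homology (multi-gene reads arise only rarely, by
chance k-mer collisions).  Passing recovery checks therefore demonstrates
the *logic* of the pipeline — QC accounting, consensus calling,
junction validation and event geometry — not robustness to error-rich
real reads; on real data the 1-mismatch budget is shared between
biological divergence and sequencing error.

# Numerical and interface choices

* Coordinates are 1-based inclusive everywhere inside the package (the
  Bioconductor convention); GFF3 is native, BED12 is converted on read.
* Determinism: every stochastic stage derives its own seed from the
  configuration seed, so a configuration maps to byte-identical FASTA,
  GFF3, FASTQ and report bundles.
* Ties and degenerate inputs: equal counts in equal libraries give p = 1
  after capping; a zero-variance background is an error for PAGE and an
  `NA` (with warning) for the qPCR correlation; zero uniquely mapped
  reads yield an empty FPKM table with a warning; single-exon genes
  contribute no junctions; planting an event in a gene with too few
  exons is skipped with a warning.
* The published-table harness (`verify_worked_examples()`) compares
  recomputed log2 ratios within the interval implied by the two-decimal
  rounding of the printed FPKM inputs, and percentages to one unit in
  the last printed decimal (one table cell differs from its printed
  value by exactly that unit, consistent with a rounding slip in the
  source table).

# Problem sizes

The default dataset (500 genes, 4 × ~44k reads) runs the full pipeline in
about a minute on one core; the bundled analysis scripts and the
acceptance script use exactly these sizes, and the test suite adds a
smaller 60-gene pipeline for structural checks.  Sizes were chosen so
that planted DE genes carry ≥ 50 expected fragments and each AS type gets
~10–20 planted events, which puts the binomial noise on recovery rates
well inside the 0.8 sensitivity margin the checks assert.

# Limitations

The no-replicate design is taken as given: the metrics test sampling
noise around a single pair of libraries, so, exactly as in the emulated
protocol, biological variability is unmodelled and the consensus rule is
the only guard against metric-specific artefacts.  Junction validation
counts presence per library, not differential usage; isoform assembly and
abundance are out of scope; GO annotations are consumed as given, without
propagation up the ontology graph.
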