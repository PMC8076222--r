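---
title: "Methods: calling and analysing 5'-overlapping gene pairs from TSS libraries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calling and analysing 5'-overlapping gene pairs from TSS libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tssoverlap)
```

## The problem

Many protein-coding genes sit head-to-head on opposite strands with their 5'
ends close together. Whether two such genes actually *overlap* — share at
least 1 bp of transcribed sequence at their 5' ends — is not a fixed property
of the genome: most genes have several alternative transcription start sites
(TSSs), and which TSS is used differs between tissues, cell lines, and
conditions. A gene pair can therefore be overlapping in one library and
non-overlapping in another, purely through promoter choice.

`tssoverlap` implements the full analysis chain around this observation:
per-library TSS admission filtering, per-library overlap calling,
clustering of the resulting pair-by-library overlap matrix, expression
statistics stratified by overlap status, allele-specific expression (ASE)
classification of overlapping versus control genes, and detection of
condition-induced promoter switches together with motif-level
transcription-factor (TF) association. A synthetic-data generator with
planted ground truth makes the whole chain testable end to end without any
external download.

## Coordinate conventions

All coordinates inside the package are 0-based half-open. BED input is
native; GFF3 (1-based inclusive) is shifted once at the parsing boundary and
never again. A gene's *annotated* 5' end equals `span_start` on `+` and
`span_end - 1` on `-`. A gene's *effective* 5' end in a library is the most
upstream admitted TSS: the minimum position on `+`, the maximum on `-`. The
3' boundary always comes from the annotation — TSS data move only 5' ends.

## TSS admission

A TSS record is admitted iff

1. it is flagged confident (the flag is taken as an input column; its
   semantics belong to the data producer),
2. its expression is at least 5 ppm (tags per million; a record at exactly
   5 ppm is admitted — the rule rejects records *below* the threshold), and
3. it lies within 5 kb of the gene's annotated 5' end.

The distance is measured as an absolute genomic distance, upstream or
downstream: the rule's purpose is to limit false TSS-to-gene assignments and
no direction is privileged, so the symmetric reading is the least-assuming
one. Records identical in (gene, library, strand, position) are merged by
summing counts before filtering. Both thresholds and the confidence
requirement are configurable through `tss_filter_config()`.

## Overlap calling

For a candidate pair (plus-strand gene with effective 5' end $a$,
minus-strand gene with effective 5' end $b$), the per-library extents are
$[a,\ \text{plus 3' boundary})$ and $[\text{minus 3' boundary},\ b]$. The
pair is called overlapping in the library iff both genes are expressed,
$b \ge a$, and each gene's effective 5' end lies inside the partner's
extent. The overlap region is then the inclusive interval $[a, b]$ with
length $b - a + 1$; the "at least 1 bp" predicate is the load-bearing part,
the length is descriptive. The inside-the-partner's-extent condition
excludes fully nested or tandem arrangements from being mistaken for
head-to-head 5' overlaps.

Candidate pairs are enumerated exhaustively from the annotation: every
(plus, minus) pair on one chromosome whose annotated 5' ends lie within
`max_gap_bp = 10000` bp. Since admitted TSSs sit within 5 kb of each
annotated 5' end, 10 kb (twice the radius) guarantees no pair capable of
overlapping under any admitted TSS choice is missed.

Alongside the verdict, the caller reports each gene's TSS multiplicity
(single/multiple) and the fraction of its admitted TSS expression initiated
inside the overlap region — genes frequently use overlapping TSSs *together
with* non-overlapping ones, so this fraction is generally below 1.

## The ternary matrix and clustering

Per-pair, per-library status is encoded as 1 (the pair used overlapping
TSSs), 0.5 (expression without overlap), and 0 (no expression). The 0.5
code is applied both when the two genes are co-expressed without overlapping
and when only one gene is expressed; the alternative — distinguishing the
single-expressed case — would leave the ternary alphabet, so the coarser
ternary reading was kept and is noted as a caveat. Only pairs with a 1
somewhere are retained as rows.

Rows and columns are clustered hierarchically with Ward's minimum-variance
criterion on Euclidean distances (`hclust` method `"ward.D2"` — the Ward
update that assumes squared Euclidean input, matching the standard "ward"
of common scientific toolkits). Euclidean distance is the natural companion
of Ward linkage; flat clusters at a chosen `k` are obtained with `cutree`,
and no default `k` is claimed — it is an exploratory parameter.

## Expression statistics

Contrast pairs are those co-expressed with overlap in at least 10 libraries
and co-expressed without overlap in at least 10 others (both bounds
inclusive). For each such pair, Pearson correlation between the two genes'
expression is computed separately within each stratum and classified
positive/negative/ns at $\alpha = 0.05$ two-sided, without multiplicity
correction — the output is a count-of-significant-pairs summary, and the
caveat is documented. The paired test compares, per gene, its mean
expression across the pair's overlapping libraries with its mean across the
non-overlapping ones (a classical paired t-test across genes; a per-pair
summed variant is available via `unit = "pair"`).

Expression values are log2(x + 1)-transformed before correlation and
t-tests: expression is heavy-tailed and the t-test assumes a roughly
symmetric location-shift scale. All functions accept `log_transform =
FALSE` for raw-scale analysis; rank-based comparisons (Mann-Whitney) are
unaffected by the monotone transform. The package accepts ppm or FPKM
tables interchangeably — the unit is the caller's declaration, not inferred.

TSS-count comparisons group every (gene, library) observation by the number
of distinct admitted TSSs (capped bin at 5+) with two-sided Mann-Whitney U
tests between adjacent groups; the six-category analysis crosses the pair's
organisation (overlap / no overlap / single expressed) with the gene's TSS
multiplicity (single / multiple) and tests all category pairs. Normal
approximation (`exact = FALSE`) is used throughout for ties-robustness.

## ASE classification

For each heterozygous SNP with read depth $\ge$ 10 (inclusive), the
minor-allele fraction $f = \min(\text{ref}, \text{alt}) / \text{depth}$
determines the class:

* $f < 0.02$ — monoallelic (at least 98% of reads from one allele, under 2%
  from the other),
* $0.02 \le f < 0.20$ — skewed,
* $f \ge 0.20$ — biallelic.

The three verbal rules are mutually consistent only when read on the minor
allele, so that formulation is used; the boundary cases ($f = 0.02$ skewed,
$f = 0.20$ biallelic) follow the "at least" wording literally. The
intervals partition $[0, 0.5]$, so every SNP receives exactly one class.

SNPs inside a pair's overlap region are excluded positionally before
classification: reads from the two superimposed transcripts mimic biallelic
signal there. The exclusion region is the union over libraries of the
pair's called overlap spans — the conservative choice, since the source
library of each RNA-seq read is a different experiment from the TSS
libraries that define the spans. A gene-library consensus requires
unanimity among its SNPs (any conflict yields `noninformative`); across
libraries, a uniform informative class is reported as such, discordant
classes yield `mixed`. Genes are analyzable only if expressed at $\ge$ 5
FPKM in at least one library and disjoint from the nondiploid mask
(copy-number changes invalidate the diploid allele-fraction thresholds).

## Promoter switches and motif association

Given disjoint control and treated library sets, a pair switches iff it is
not overlapping in *every* control library and overlapping in *every*
treated library (a universal quantifier on both sides). A gene of such a
pair is a switching gene when its condition-level effective 5' end (most
upstream across the condition's libraries) moved; the shift is reported
strand-aware (positive = upstream) and the event records whether the old
TSS is still used in the treated condition (an *additional* promoter rather
than a replacement).

Differential-expression calls are consumed, not fitted: genes with
log2 fold-change strictly above 1.5 (or strictly below −1.5) and FDR
strictly below 0.05 form the up/down sets, intersected with a TF list.
Promoter sequences are scanned with PFM-derived position weight matrices:
counts are converted to log2 odds with total pseudocount 0.8 distributed by
a uniform background (conventional defaults; both configurable and recorded
in output metadata), and a window is a hit when its min–max relative score
$(s - s_{\min}) / (s_{\max} - s_{\min})$ reaches 0.95 — the standard
"relative score" semantics of PWM scanning tools. Both strands are scanned;
windows containing non-ACGT characters are skipped; reverse-strand hits are
reported on forward coordinates.

A TF is associated with a TSS when any of its hits has its midpoint within
500 bp (inclusive, symmetric); the midpoint anchor is used because no
convention fixes the anchor, with edge-anchoring available via
`anchor = "edge"`. A TF associated with exactly one of a gene's TSSs is
TSS-specific — the signature of interest for a newly activated promoter
gaining an activator site.

## Local enrichment

Gene-set enrichment is a one-sided hypergeometric test within an explicit
universe, with sets sharing fewer than 4 genes with the query dropped
before testing, Benjamini–Hochberg FDR across the reported sets, and
results ordered by the sum of $-\log_{10} p$ and $-\log_{10}\text{FDR}$.
This replaces any external enrichment service with a transparent local
computation while preserving the minimum-overlap rule and the
$-\log_{10}$ reporting scale.

## The synthetic generator

`simulate_dataset()` emits every input the pipeline consumes, with planted
truth for every property scored downstream. Its defaults define the
standard validation scenario:

* **Geometry.** 200 head-to-head pairs, each with a fixed local geometry:
  the plus gene has an upstream overlap-creating TSS and an internal TSS
  1.3 kb downstream; the minus gene mirrors this. The pair overlaps exactly
  when an overlap-creating TSS is used, with overlap lengths of roughly
  0.1–1.9 kb depending on the TSS combination. Noise TSS rows (sub-5-ppm,
  beyond-5-kb, and non-confident records, all positioned to corrupt
  effective 5' ends if admitted) exercise the filter.
* **Library groups.** Three groups of 10 libraries. The group propensity
  (0.9 within a pair's own group, 0.4 elsewhere) is the per-cell
  probability that the pair uses overlapping TSSs in that library; using
  overlapping TSSs entails both genes being expressed, so expression
  dropout (per-gene probability 0.9) applies only to non-overlap cells.
  This makes the expected matrix-cell agreement equal the configured
  propensities. Five pairs are constitutive: they overlap wherever
  co-expressed.
* **Expression.** log2 expression is Gaussian with mean 5 and SD 1 per
  gene-library, an additive uplift of 0.5 log2 units in cells where the
  pair overlaps, and within-pair correlation $\rho = 0.5$ induced by a
  shared latent factor per (pair, library) — the simplest mechanism giving
  a controllable Pearson correlation.
* **ASE.** Planted minor fractions 0.005 / 0.10 / 0.45 for
  monoallelic / skewed / biallelic straddle the 2% and 20% thresholds with
  margin; class mixture 0.07 / 0.10 / 0.73 / 0.10 (the last being `mixed`
  genes with discordant per-library classes), echoing the roughly 1:10
  monoallelic:biallelic composition typical of such surveys. Depth is
  100 + Poisson(20): at the monoallelic fraction, the expected minor-allele
  count must be resolvable against the 2% boundary, which requires depths
  in the low hundreds — typical of ASE-grade RNA-seq at expressed genes —
  whereas depth near 30 leaves the binomial upper tail above 2% too heavy.
  Planted decoys: SNPs inside overlap regions emitting pseudo-biallelic
  signal, and depth-5 SNPs below the depth floor.
* **Switch arm.** Two control and four treated libraries. Regular pairs
  respond identically in both conditions (one draw per pair), so only the 8
  planted switch pairs — alternating plus-gene, minus-gene, and both-gene
  switches, giving upstream shifts on both strands — can satisfy the
  universal quantifiers; recovery is therefore exactly
  precision = recall = 1 when the caller is correct.
* **Motifs.** PFMs are synthetic 12-mers with an 85:5 consensus:other
  count ratio; at the 0.95 relative-score threshold only the exact
  consensus scores as a hit, so planted instances (activator consensus
  within 500 bp of the new TSS, repressor near the old one, both placed
  > 500 bp from the other TSS) are recovered without calibrating against
  chance hits. The DE table marks switching genes and the planted activator
  up, the planted repressor down.

What the generator does *not* emulate — and what passing tests therefore do
not show about real data: mapping and peak-calling artefacts in TSS calls,
reference bias in allele counts, overdispersed (non-binomial) allele
sampling, correlated expression beyond the single shared factor, realistic
promoter sequence composition (background is i.i.d. uniform ACGT), linked
SNPs, and any count-model uncertainty in the consumed DE table.

## Numerical and degenerate-input choices

Threshold boundaries follow the quoted rules literally: ppm $\ge 5$ admit,
distance $\le 5000$ admit, depth $\ge 10$ retain, FPKM $\ge 5$ expressed,
DE thresholds strict. Zero-variance expression yields an `ns` correlation
verdict with `r = NA` rather than an error; a zero-variance paired
difference yields $t = 0, p = 1$ (or $\pm\infty, p = 0$ for a constant
nonzero shift). Single-row or single-column matrices cluster degenerately
without error. Empty masks answer membership queries with `FALSE`. Library
means over zero genes are flagged `NA`. All pipeline stages are
deterministic given their inputs; the only randomness in the package is the
generator's, driven entirely by one seed.

## Validation scales

The test suite validates each operation against independent oracles
(explicit base-set intersection for overlap calling, per-record predicate
re-evaluation for filtering, exhaustive count-pair enumeration to depth 200
for ASE, definitional sums for Pearson and Mann-Whitney, window-by-window
rescoring and exhaustive 4^L word enumeration for PWM scanning, direct
hypergeometric tail sums for enrichment) and checks planted-truth recovery
on the default scenario: 200 pairs × 30 main libraries plus the 6-library
switch arm, 20 seeds for clustering recovery, 1000 random geometries for
the overlap oracle, 1000 SNPs per ASE class, and 200 replicates for the
paired-test power check (0.5-log2-unit uplift, unit-SD stratum means, 73
gene units). These sizes were chosen to make recovery statistics stable at
desk scale while keeping the suite fast.
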