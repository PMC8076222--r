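# tssoverlap

Analysis of head-to-head protein-coding gene pairs that overlap at their 5'
ends depending on which transcription start sites (TSSs) each library uses.

## The problem

Alternative promoters make gene overlap a *state*, not a genome property:
two genes on opposite strands with nearby 5' ends may share transcribed
sequence in one tissue and not in another, purely through TSS choice. This
matters for transcriptional interference (head-to-head polymerase
collision), for sense/antisense RNA pairing, and for interpreting
condition-induced promoter switches. `tssoverlap` is for researchers with
per-library TSS tables (TSS-seq/CAGE-style), gene-level expression, and
optionally allele-level read counts, who want to call and analyse
5'-overlap status per library.

## The method

For each gene and library, the **effective 5' end** is the most upstream
admitted TSS — admitted meaning: flagged confident, expression ≥ 5 ppm, and
within 5 kb of the annotated 5' end. With `a` the plus gene's effective 5'
end and `b` the minus gene's (0-based), the per-library extents are
`[a, plus 3' boundary)` and `[minus 3' boundary, b]`; the pair **overlaps**
iff both genes are expressed, `b ≥ a`, and each effective 5' end lies inside
the partner's extent — i.e. the pair shares ≥ 1 bp at its 5' ends, with
overlap length `b − a + 1`.

Downstream analyses:

* **Matrix + clustering** — pair × library matrix over {0, 0.5, 1}
  (no expression / expression without overlap / overlapping TSSs used),
  Ward clustering (`ward.D2`, Euclidean) of both axes.
* **Expression** — pairs overlapping in ≥ 10 and non-overlapping in ≥ 10
  libraries; per-stratum Pearson correlation classes; a paired t-test of
  per-gene mean expression with vs without overlap; Mann-Whitney
  comparisons by TSS count and by organisation × TSS-count category.
* **ASE** — per-SNP classification by minor-allele fraction
  `f = min(ref, alt)/depth`: monoallelic (`f < 0.02`), skewed
  (`0.02 ≤ f < 0.20`), biallelic (`f ≥ 0.20`); depth ≥ 10; SNPs inside
  overlap regions excluded; unanimity per gene-library, `mixed` across
  discordant libraries; nondiploid and sub-5-FPKM genes excluded.
* **Switches** — pairs non-overlapping in *all* control and overlapping in
  *all* treated libraries; strand-aware upstream TSS shifts; consumed DE
  tables thresholded at |log2FC| > 1.5, FDR < 0.05; PWM promoter scanning
  (min-max relative score ≥ 0.95) and TSS-specific TF association within
  ± 500 bp.
* **Enrichment** — local one-sided hypergeometric test with minimum overlap
  4 and BH FDR.
* **Synthetic data** — `simulate_dataset()` generates all inputs with
  planted ground truth (library-group overlap propensities, expression
  uplift and correlation, binomial allele counts, promoter switches,
  planted motifs); `truth_compare()` scores recovery.

## Worked example

```r
library(tssoverlap)
sim <- simulate_dataset(sim_config(seed = 1))  # default 200-pair scenario
res <- run_pipeline(sim)

nrow(res$matrix)                               # pairs overlapping somewhere
length(res$summary$always_overlap_pairs)       # constitutively overlapping
nrow(res$contrasts)                            # >=10 / >=10 contrast pairs
res$paired_test[c("t", "p")]
table(res$correlations$class[res$correlations$stratum == "overlap"])
unique(res$switches$pair_id)
truth_compare(sim, res)$clustering_ari
```

Output on this scenario:

```
pairs overlapping in >=1 library: 208
always-overlap pairs: 5
contrast pairs (>=10/>=10): 168
paired t-test: t = 28.79 , p = 1.29e-92
      ns positive
      72       96
switch events (pairs): 8
clustering ARI: 1
```

Reading: all 208 candidate pairs use overlapping TSSs in at least one
library, but only the 5 planted constitutive pairs overlap *whenever*
co-expressed. Genes are significantly more highly expressed in libraries
where their pair overlaps (the planted 0.5-log2 uplift; positive t), most
significant expression correlations between partners are positive (the
planted within-pair correlation), the 8 planted promoter switches are all
recovered, and Ward clustering of the 0/0.5/1 matrix reconstructs the three
planted library groups exactly (adjusted Rand index 1).

File-based runs write per-stage TSVs and a JSON manifest:

```r
out <- run_all(sim_config(seed = 1), dir = "my_run")
```

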