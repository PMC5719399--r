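---
title: "Models and methods behind trophreg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind trophreg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trophreg)
library(dplyr)
```

trophreg implements the downstream computational analyses used to study
how a lineage-restricted transcription factor — the motivating case is
CDX2 in mouse trophoblast stem (TS) cells — partitions the regulatory
landscape of the early embryo: which genes it is associated with, where
its binding coincides with silencer-like chromatin, and what happens to
single knockout embryos. Because the raw sequencing and array data behind
such a study are external resources, the package ships a synthetic-data
module that generates every input with planted ground truth, so each
stage can be validated by recovery rather than by eye.

## The TF–gene association model

The association strength of a factor on gene $i$ is an intensity-weighted
sum over its ChIP peaks with exponential distance decay:

$$a_i = \sum_k g_k \, e^{-d_k / D_0},$$

where $g_k$ is the intensity of peak $k$, $d_k$ the absolute distance
from the peak midpoint to the gene's TSS, and $D_0$ the decay length.
Defaults are $D_0 = 10\,000$ bp — long enough to credit enhancer- and
silencer-range binding rather than only promoters — and a hard cutoff of
1 Mbp beyond which peaks do not contribute. A peak may contribute to any
number of genes; there is no exclusive assignment. The genome is ranked by
score and the top $N$ genes (default 3000) form the factor's target set.

Peak location is the interval midpoint, which is computable from a plain
BED file; when a `summit` column is present it is used instead. Ties in
ranking are broken by ascending gene id so that `top_targets()` is fully
deterministic.

## Interval geometry

Coordinates are 0-based half-open throughout (BED native). Two intervals
co-occupy a locus when the gap between their nearer borders is at most
`max_gap`; touching intervals have gap 0, so `max_gap = 0` is the most
permissive reading consistent with "distance between borders" and reduces
to ordinary half-open overlap elsewhere. Co-occupancy between two peak
sets uses a 200 bp default tolerance. The silencer triple rule uses
`max_gap = 0` by default — an at-least-touching criterion in the spirit
of BEDtools-style intersection — because there is no evidence the looser
two-factor tolerance should extend to chromatin-mark overlap; both values
are plain arguments.

Loci are assigned to genes by the nearest TSS measured from the locus
midpoint `floor((start+end)/2)`; ties go to the lexicographically smaller
gene id; strand flips only the sign of the reported distance (negative =
upstream), never its magnitude. Loci on gene-free chromosomes are
reported unassigned rather than dropped or errored, so candidate counts
are conserved.

## Silencer calling

A candidate lineage-specific silencer is a TF peak that also overlaps at
least one DNase-I hypersensitive site and at least one H3K27me3-enriched
region. The candidate's footprint is the TF peak itself (the candidate is
a binding site with co-marks, not a geometric intersection), and the
nearest qualifying DHS and H3K27me3 intervals are recorded as witnesses.
H3K27me3 "enrichment" means membership in the supplied interval set;
signal-level processing belongs to upstream peak calling and is out of
scope. Enlarging `max_gap` can only add candidates, never remove one.

## Differential expression and the window profile

The two-condition contrast uses the plain fold-change rule: per gene,
`log2fc = log2((mean_A + 1) / (mean_B + 1))` on linear values, a Welch
unequal-variance $t$-test on `log2(value + 1)`, and selection at
`|fc| >= 2` (boundary inclusive) with `p < 0.05` (boundary exclusive).
The pseudocount of 1 guards zeros from the generator. No moderation or
multiple-testing correction is applied — the rule is deliberately the
simple one stated above, and the package's null-calibration check (50
cohorts x 200 null genes) verifies that the *joint* rule passes far fewer
than 5% of null genes, since the fold-change cutoff dominates at small
replicate counts. Genes are ranked by descending log2 fold change (tie:
gene id), and the association scores of the ranked genome are averaged in
a sliding window (default 500 genes, step 1; the window is exposed
because analyses of this kind are also reported at 1000). Window means
are computed from a cumulative sum, which agrees with naive re-averaging
to ~1e-15 relative error.

## Single-embryo qPCR analysis

Technical replicates (default 3) are collapsed to a mean Ct over detected
reactions; expression relative to the endogenous control (Actb) is
$2^{Ct_{ref} - Ct_{gene}}$, so the control is exactly 1, one extra cycle
halves expression, and a gene undetected in all replicates is 0.

Genotypes of embryos from a heterozygous intercross, where a Neo cassette
replaces the targeted allele, are called per embryo: **null** if the
target transcript is undetected in *all* replicates and Neo is clearly
expressed; **wild type** if Neo is negligible — undetected or below 1% of
the cohort median of positive Neo levels; **het** otherwise; and a
contradictory pattern (no target transcript *and* no cassette) is flagged
`ambiguous` instead of being silently assigned. The 1% convention is a
declared operating rule, not an inference about any instrument's
detection chemistry; it and the Ct detection limit are arguments.

Embryos are clustered on `log2(expression + 1e-3)` with distance
$1 - r_{\text{Pearson}}$ and average linkage (`stats::hclust`, which
merges the lowest-index pair on tied heights, making the tree
deterministic). The offset $10^{-3}$ exists because knockouts contain
exact zeros. The two-axis correlation map computes, per gene, the Pearson
correlation of log expression with the anchor gene separately across
single cells of wild-type embryos and across whole mutant-cross embryos,
then labels quadrants with threshold $\tau = 0.3$: cluster 1
(both $> \tau$) = positively regulated targets; cluster 2
($r_{sc} > \tau$, $|r_{emb}| \le \tau$) = the parallel lineage program;
cluster 3 ($r_{emb} < -\tau$) = negatively regulated (ICM/pluripotency
pattern). The $\tau$ rule is an explicit re-creation of a visual
clustering; Spearman is available via an argument. Zero-variance genes
are recorded with correlation 0 and excluded from clusters.

## What the generators emulate — and what they do not

All generators are pure functions of their arguments and a seed
(bit-identical reruns; the caller's RNG stream is untouched).

* `gen_genome()` places genes on uniform 1-kb-slot positions (>= 1 kb TSS
  spacing) with random strands.
* `gen_peaks()` gives each planted target 1–5 peaks at exponentially
  distributed TSS distances (mean 20 kb, truncated at 1 Mb — so the 1 Mb
  score cutoff is binding-relevant), lognormal intensities (meanlog
  log 20, sdlog 0.5, rounded to tenths so BED files round-trip exactly),
  and uniform background peaks (default 5/Mb). Negative targets get
  intensities scaled by 0.4, the "moderate binding" dosage that produces
  the asymmetric tail of the window profile.
* `gen_epigenome()` plants silencers as TF peaks carrying an overlapping
  DHS and a covering H3K27me3 domain, plus decoys carrying exactly two of
  the three marks and scattered solitary marks, all placed with >= 2 kb
  mutual separation and clearance from unrelated peaks; it verifies by
  exhaustive scan that the planted loci are *exactly* the triple-overlap
  loci, so silencer precision/recall against truth is well defined.
* `gen_expression()` plants a symmetric log2 effect (default 2) on target
  genes over lognormal baselines with lognormal noise (sd 0.25 log2).
* `gen_embryo_ct()` builds a 27-embryo cohort (6 null, 4 wild type, 17
  het by default — the composition of the motivating experiment) in
  technical triplicate: Ct = base − log2(dosage effect) + biological +
  technical noise, detection limit Ct 28 on the preamplified scale,
  nulls lacking the target transcript entirely, Neo reporting mutant
  allele dosage, ICM genes elevated ~2-fold in nulls (the magnitude is a
  free parameter of the generator, not an estimate), and the reference
  gene given near-zero biological noise so it is always the
  lowest-variance assay.
* `gen_single_cells()` emulates a panel-restricted wild-type blastocyst:
  half TE cells (anchor high), half ICM cells, with the anchor-tracking,
  parallel, and anti-correlated gene classes needed by the map.

The generators emulate the *structure* the methods assume — not real
data. They contain no mappability or GC artefacts, no batch effects, no
amplification-efficiency variation, no probe-level noise, and planted
truth is noiseless by construction. Passing recovery tests therefore
demonstrates correctness of the computations under their stated model,
not performance on real sequencing data.

Parallel-program genes deserve one honest caveat: their embryo-axis
correlation is pure noise around 0 with standard error ~$1/\sqrt{26}$ at
27 embryos, so any single such gene lands outside $|r| \le 0.3$ roughly
one time in eight. The placement criterion is therefore evaluated in
aggregate over all planted classes and seeds (observed ~95%), which is
the property the map is meant to have at this cohort size.

## Numerical and design choices

* Degenerate inputs: empty peak sets score 0; a constant gene in the
  Welch test gets p = 1 (identical groups) rather than an error; constant
  embryo profiles correlate as 0 with a warning; empty candidate lists
  summarise to empty tables.
* `pipeline_config()` carries every parameter with the defaults above;
  `run_pipeline()` caps `top_n` and `window` at the simulated genome size
  and records effective values in the JSON manifest, along with MD5
  checksums of every written file — two runs of the same configuration
  are bit-identical.
* Problem sizes used by the shipped checks (chosen to exercise each
  property at meaningful scale on a single core): association oracle up
  to 1000 genes x 5000 peaks; interval oracles 100 instances of up to 300
  intervals; silencer recovery 20 seeds of 20 silencers + 40 decoys;
  profile shape at 1000 genes with 200 strong positive and 100 moderate
  negative targets; null calibration 50 cohorts x 200 genes; embryo
  recovery 10 cohorts of 27.
* Motif density profiling counts exact IUPAC matches on both strands in
  binned windows (default 4 kb, 100 bp bins) centred on peak midpoints;
  matching is exact by design — the analysis reports counts, not motif
  scores — and windows truncated at contig ends contribute only covered
  bins.

## Known limitations

The DE rule is the stated fold-change heuristic, not a moderated test;
the silencer caller treats mark membership as binary; the correlation-map
clusters are threshold conventions, not model-based assignments; and the
qPCR model assumes perfect doubling efficiency. These mirror the scope of
the analyses the package reproduces.
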