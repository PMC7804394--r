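---
title: "Methods: integrating accessibility, Polycomb marks and expression"
author: "pcgaccess"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrating accessibility, Polycomb marks and expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## Scope

`pcgaccess` implements the integrative analysis used to relate chromatin
accessibility (ATAC-seq), the Polycomb-deposited histone marks H2AK121ub
and H3K27me3 (ChIP-seq), and gene expression across a wild type (WT) and a
panel of Polycomb-group mutants. It also ships a synthetic-data generator
that plants known structure at every layer, which is how the package tests
itself: every analysis stage must recover what the generator planted,
within stated statistical tolerances.

This vignette documents the statistical methods, the generator's model and
defaults, and the numerical conventions.

## Coordinate conventions

On disk all region formats are BED-convention (0-based, half-open); in
memory everything is a `GenomicRanges::GRanges` (1-based, closed). The
conversion happens in exactly two places: the `regions()` constructor and
the file readers/writers. Nothing else in the package touches raw
coordinates.

One consequence worth spelling out: two intervals that merely *touch* (BED
`end == start`) share no base pair. They are merged by `merge_regions()` at
`gap = 0`, they are 0 bp apart for `nearest_distance()`, and they do *not*
count as overlapping for `count_overlaps()` or `intersect_regions()`. The
test suite pins this behaviour against per-base boolean-mask oracles.

## Consensus THS construction

A genotype's Tn5 hypersensitive sites (THSs) are the base-pair intersection
of its two replicate peak sets, merged into disjoint regions
(`genotype_ths()`): a region must show signal accumulation in both
replicates. Blacklisted bases are removed at region level before merging
across genotypes. The consensus set (`build_consensus()`) is the merged
union of the per-genotype sets; each consensus region records which
genotypes contributed (`provenance`, `n_genotypes`).

Two filters then apply:

- **Signal filter** (`filter_matrix()`): a region is kept when its maximum
  CPM across samples reaches the lower 5th percentile of the pooled
  accessibility-matrix entries (or a fixed CPM threshold).
- **q-value confidence** (`consensus_qpass()`): a genotype "q-passes" a
  region when *both* of its replicates contain an overlapping peak with
  q < 0.05; regions q-passing in no genotype are dropped.

Signal over a region is always the length-weighted mean CPM of a
piecewise-constant track (`track_mean()`), with uncovered bases counting as
0 CPM, so the denominator is the full region width.

## Distance-interval mark association

For each consensus THS, `distance_bin_percentages()` bins the edge-to-edge
distance to the nearest mark peak into *overlap* (distance 0), the gap
intervals (0,100], (100,500], (500,1000], (1000,2000] bp, and a terminal
bin for THSs with no peak within 2 kb (or none on their chromosome). A
cumulative "within d bp" summary is also emitted. `colocalization_venn()`
classifies each THS by whether each of two marks lies within 2 kb, giving
the four Venn cells and co-localization shares such as "the fraction of
H3K27me3-associated THSs that are also H2AK121ub-associated".

## Monte Carlo enrichment

`mc_enrichment_test()` asks whether a feature set (e.g. transcription
factor binding sites) concentrates at THSs. The observed statistic is the
*median per-region feature overlap count*. The null is built from sets of
random regions matched in number and in the exact multiset of lengths:

- each random region draws a chromosome with probability proportional to
  its number of feasible start positions (length − width + 1), then a
  uniform start — uniform placement over all feasible positions;
- random regions may overlap each other (matching a shuffle without
  self-exclusion);
- regions overlapping an exclusion set (the blacklist) are rejected and
  resampled.

The empirical p-value uses the add-one rule
$p = (1 + \#\{null \ge obs\})/(n_{sets}+1)$: it is never exactly 0, and its
floor $1/(n_{sets}+1)$ is the honest way to report "p below the Monte Carlo
resolution". The enrichment ratio is observed over the mean of the null
medians. Calibration under a planted null (factor 1) and recovery of a
planted factor 5 are both part of the acceptance tests; note the median
statistic makes the test conservative at coarse feature densities (ties in
the null), which the calibration test tolerates by checking
$P(p \le \alpha) \le \alpha + 3\,SE$ rather than equality.

## Mark levels relative to WT

Peaks are assigned to a gene when they overlap its gene body or its
promoter — the 750 bp immediately upstream of the TSS, strand-aware
(`assign_peaks_to_genes()`). A gene's signal per sample is the
length-weighted mean CPM over the base-pair union of its peaks
(`gene_mark_table()`), and the linear ratio mean(mutant)/mean(WT) is binned
left-closed into percent-of-WT classes: `<20%`, `20-40%`, `40-60%`,
`60-80%`, `80-120%` (WT-like), `>120%` (`classify_levels()`).

The "<60% of WT" superset used by the integration corresponds in log2
space to `log2fc < log2(0.6) = -0.7370`, i.e. the printed two-decimal
cutoff −0.74 (`wt_fraction_cutoff_log2()`).

## The moderated t-statistic

All differential comparisons (accessibility, mark levels, expression) use
`moderated_diff()`: a row-wise two-group comparison on
$\log_2(\mathrm{CPM} + 0.5)$ with empirical-Bayes variance shrinkage.
Per row, the pooled variance $s_g^2$ (df $d_g = n_a + n_b - 2$) is shrunk to

$$\tilde s_g^2 = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g}$$

and the t-statistic referred to $t_{d_0 + d_g}$. Two design choices:

- **Fixed prior df** $d_0 = 4$ rather than estimated. At 2–3 replicates,
  estimating $d_0$ is unstable and makes results depend on the whole
  matrix in opaque ways; fixing it keeps the statistic deterministic and
  still gives the small-sample stabilisation that motivates moderation.
  Setting `d0 = 0` recovers the ordinary pooled t-test exactly (tested to
  $10^{-10}$).
- **Bias-corrected prior scale.** Under the scaled-inverse-$\chi^2$ prior,
  the sample variances satisfy $E[s_g^2] = s_0^2\, d_0/(d_0-2)$, so the
  naive plug-in $s_0^2 = \mathrm{mean}(s_g^2)$ is biased upward and the
  null t is visibly non-uniform at a few thousand rows. The package uses
  $s_0^2 = \mathrm{mean}(s_g^2)\,(d_0-2)/d_0$. With gene-wise variances
  drawn from the matching scaled-inverse-$\chi^2$ family — i.e. realistic
  gene-to-gene noise heterogeneity — the null p-values are exactly
  $t_{d_0+d_g}$-distributed, which the test suite checks by
  Kolmogorov–Smirnov at 2,000 genes.

Expression classification (`classify_expression()`) calls a gene
*activated* when $\log_2 FC \ge 1$ (boundary inclusive) with $p < 0.05$
(strict), *repressed* symmetrically, else *unaltered*. Differential
accessibility (`differential_accessibility()`) uses $p < 0.05$ with no
fold-change floor and reports increased/decreased/unchanged.

For group comparisons of per-gene scalars (e.g. TSS-window accessibility
of mark-loss genes versus WT-like genes), `profile_group_test()` uses the
one-sided Mann–Whitney rank-sum test: exact when both groups are small
(min n ≤ 8) and untied — validated against full enumeration — and the
tie-corrected normal approximation otherwise.

## Integration

`gene_ths_pairing()` pairs each gene with the consensus THSs overlapping
its body/promoter scope and averages their accessibility rows.
`integration_table()` then restricts to genes of one Polycomb category
whose mark level fell below 60% of WT and whose accessibility changed, and
cross-tabulates accessibility direction against expression class; the six
percentages sum to 100 and every exclusion is tallied. `scatter_table()`
emits the per-gene triples behind level-versus-accessibility scatter
plots.

## The synthetic-data generator

`sim_spec()` bundles every tunable; `simulate_dataset()` composes the
layers into one coherent study, each layer on its own deterministic
sub-stream of the seed, so any layer can also be simulated in isolation.

| Layer | Planted structure (defaults) |
|---|---|
| Genome | 5 chromosomes × 2 Mb |
| Genes | 1,000 fixed-length genes on a regular grid, random strand |
| Categories | only-H2AK121ub 15%, both 20%, only-H3K27me3 10%, non-PcG 55% |
| WT mark peaks | H2AK121ub ~500 bp at the TSS; H3K27me3 over the gene body; a second, edge-jittered dataset per mark |
| Mark levels | per-gene multipliers from {0.1, 0.3, 0.5, 0.7, 1.0, 1.5}; replicate noise sd 0.1 on log2 |
| THSs | 1,000 log-normal-length sites, 70% at promoters (PcG-marked genes weighted 4:1), the rest intergenic, disjoint |
| ATAC replicates | boundary jitter sd 20 bp, 5% drop-outs, MACS2-style q-values |
| Accessibility | base 8 CPM at THSs over 0.5 CPM background; ×1.8 at THSs of mark-loss genes in that mutant |
| Mark distances | per-THS distance-bin assignment; H2AK121ub mass 0.5 within 100 bp and 0.8 within 2 kb; H3K27me3 mass 0.4 with 96% drawn from H2AK121ub-associated THSs |
| TFBS | 10,000 fixed-width sites, density inside THSs 5× outside |
| Expression | mark-loss genes activated with probability 0.4, else unaltered; 5% background DE |
| Blacklist | 10 × 1 kb regions placed away from all features |

Two derivations worth recording:

- **Exact TFBS density mixture.** To plant density ratio $f$ with $T$ THS
  bases in a $G$-base genome, a site's midpoint falls inside THS bases with
  probability $q = fT/(fT + (G-T))$ and uniformly within its component.
  Then (density inside)/(density outside) $= (q/T)/((1-q)/(G-T)) = f$
  exactly, for any $f \ge 0$; $f = 1$ is uniform placement.
- **Distance planting.** Each THS is assigned to *overlap*, one gap bin,
  or *none* by the mark's bin probabilities; a peak of mark-specific
  log-normal length is then placed at a distance drawn uniformly within the
  assigned bin, on a random side (flipping at chromosome edges). Recovery
  is checked at 2,000 THSs on a sparse genome so that neighbouring THSs'
  peaks rarely contaminate the measured distances.

## Problem sizes

Defaults are desk-scale by design: the full pipeline on the default spec
runs in well under a minute of simulation plus analysis on one CPU, and
the entire test suite (including Monte Carlo calibration over 200 null
datasets and an end-to-end run) takes a few minutes. All sizes are
ordinary `sim_spec()` fields, so larger studies are a parameter change,
not a code change.

## Other design decisions

- **Blacklist at region level**: blacklisted bases are subtracted from
  per-genotype THSs before consensus (rather than dropping whole regions),
  and the Monte Carlo placement rejects random regions overlapping the
  blacklist, keeping observed and null spaces comparable.
- **Replicate q-pass rule**: "both replicates overlap a q < 0.05 peak" is
  deliberately stricter than "any replicate", matching the
  intersection-based THS definition.
- **YAML configuration** with a mandatory seed; every CLI run writes a
  `run_manifest.yaml` with the package version, seed and thresholds.
- **GRanges internally**: the package builds on the GenomicRanges stack
  rather than re-implementing interval trees; the BED↔GRanges conversion
  is confined to constructors and IO, and the interval semantics are
  pinned by mask/all-pairs oracle tests.

## Limitations

- The generator plants *region-level* structure; it does not model reads,
  fragment-length distributions, GC bias or mappability.
- Replicate structure is fixed at two ATAC/mark replicates per genotype
  (the supported design); `genotype_ths()` errors on other counts rather
  than guessing a rule.
- The moderated model assumes independent genes; correlated blocks (e.g.
  clustered gene families) would make the null slightly optimistic.
- Distance planting is per-THS independent; at high THS density the
  measured distance distribution is a convolution of the planted one with
  neighbour contamination (kept negligible in the tests by spacing).
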