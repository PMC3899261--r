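---
title: "Evaluating RT-qPCR reference genes with refstab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating RT-qPCR reference genes with refstab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refstab)
```

## The problem

Relative RT-qPCR quantification reports a target gene's expression as a
ratio to one or more reference genes assumed stable across the samples
compared.  That assumption fails often enough — classical housekeeping
genes drift across tissues, developmental stages and stress conditions —
that references must be validated per species, tissue panel and
experimental design.  `refstab` implements the three stability
estimators in routine use, the quantification steps feeding them, the
geometric-mean multi-gene normalization they motivate, and a synthetic
data generator that makes every stage testable against known ground
truth.

Throughout, the data model is: threshold cycles `Ct` per (sample, gene
region, replicate well), a sample-to-group map (e.g. tissue types), and
optionally a dilution series per region.  "Region" rather than "gene"
because candidate panels typically include several amplicons per gene —
within the coding sequence (CDS), which may co-amplify homologous loci,
and within the gene-specific 3'-UTR.

## Quantification

A dilution series of known relative quantities `Q` (default five decade
steps, 100 … 0.01) is fit by ordinary least squares as
`Ct = b + m·log10 Q`; the amplification efficiency is
`E = 10^(−1/m) − 1`, so perfect doubling gives `m = −3.3219`, `E = 1`.
We fit unweighted OLS: replicate wells enter individually, and no
heteroscedasticity model is imposed — dilution noise in practice is
dominated by pipetting, roughly constant on the Ct scale.  Unknown Cts
invert the curve, `q = 10^((Ct − b)/m)`.  A region without a curve can
fall back to an assumed efficiency, in which case quantities are
expressed relative to the region's mean Ct (`q = (1+E)^(mean Ct − Ct)`);
every stability statistic below is invariant to that choice of anchor.

For two amplicons of the same gene read at a shared fluorescence
threshold `T` (baseline-subtracted Rn, default 0.3), the initial
template amount is `Q0 = T/(1+E)^Ct` and the CDS : UTR ratio
`Q0_cds/Q0_utr` diagnoses two effects: ratios above 1 indicate CDS
primers amplifying several homologous loci; ratios depressed in a group
whose cDNA was synthesized with oligo-dT primers indicate depletion of
template far from the poly-A tail.  The threshold cancels when shared,
but is carried explicitly so region-specific thresholds remain possible.

## The three stability estimators

**geNorm.**  For regions *j*, *k*, `V_jk` is the sample standard
deviation (n−1 denominator throughout the package) of `log2(q_j/q_k)`
over the samples where both are usable; `M_j` is the mean of `V_jk` over
partners.  The least stable region (highest M) is removed and M
recomputed until three remain; the surviving trio is reported as a set
with its per-region M and their mean (`trio_m`), since at three genes
the elimination criterion no longer separates them.  Exact ties in M are
broken by removing the lexicographically last region name — arbitrary
but deterministic, and recorded in the trace.  `V_jk` only sees
within-sample ratios, so per-sample loading differences cancel exactly;
this is the property that makes M meaningful without prior
normalization.

**NF and V_n/n+1.**  The normalization factor `NF_n` is the per-sample
geometric mean of the `n` best regions.  `V_n/n+1 = SD(log2
NF_n/NF_{n+1}))` measures how much the factor still moves when the next
gene is added; below the conventional cutoff 0.15, `n` references are
deemed sufficient.  The smallest such `n` is reported; with typical
panels the practical question is whether `V_3/4 < 0.15`.

**Model-based ranking (NormFinder).**  Log2 quantities within group *g*
are modelled as sample effect + gene-by-group deviation `d_ig` + noise
with gene-specific variance `σ²_ig`.  Subtracting per-sample means
removes loading, but contaminates each gene's residual with `1/n` of
every other gene's noise; with `n` genes the naive residual variance
satisfies `E[s²_i] = σ²_i(1 − 2/n) + mean(σ²)/n`.  We solve this in
closed form, `σ̂²_i = (s²_i − S/(n(n−1)))·n/(n−2)` with `S = Σ s²`, and
truncate negative estimates at zero (method-of-moments practice; it also
makes an exactly sample-tracking gene score 0).  Group deviations are
centred per gene across groups — a gene uniformly offset in *every*
group is absorbed into its overall level and is not penalized — and
shrunk toward zero by `γ²/(γ² + Var(d̂))`, where `γ²` is the
method-of-moments estimate of the true between-group deviation variance
(truncated at zero).  The stability value is the group average of the
error budget of using the gene as reference for a new sample,

```
ρ_i = mean_g ( |d̃_ig| + sqrt( σ̂²_ig + shrunken Var(d̂_ig) ) ),
```

which reduces *exactly* to the single-group measure `sqrt(σ̂²_i)` when no
between-group variation is detectable — a property we consider essential
for a screen that must degrade gracefully on homogeneous panels.  The
best two-gene combination minimizes the same budget for the averaged
pair, `|mean d̃| + sqrt((v_i + v_k)/4)`; opposite-sign deviations cancel,
which is why the model-based best pair can differ from the top two
single genes.  Per-group "intra-group stability" tables are single-group
runs on each group's sample subset.

**ΔCt.**  Regions are ranked by the mean over partners of
`SD(Ct_j − Ct_k)`.  Since `log2 q = −Ct` up to an affine map at 100 %
efficiency, ΔCt pair SDs equal geNorm `V_jk` on quantities `2^(−Ct)`
exactly — a bridge asserted to 1e−12 in the test suite.  Its virtue is
needing no curves, so it is the recommended first pass over large
candidate panels (`screen_candidates()`, default keep = 6) before the
curve-based methods.  Its documented blind spot: efficiency differences
between regions are ignored.  An optional pre-filter keeps one region
per gene (narrowest Ct interquartile range) so trivially correlated
homologue amplicons cannot crowd the shortlist.

## Handling of missing data, masks and runs

Undetermined wells (no amplification within `max_cycles`, default 40)
are an explicit sentinel, distinct from absent rows; they are excluded
from replicate aggregation, and a fully undetermined cell collapses to
missing.  Replicates collapse by the arithmetic mean of Ct (median
offered for robustness); wells spanning more than `max_spread` cycles
(default 1) are flagged, never dropped — QC is advisory.  Two
independent analytical runs merge by averaging collapsed Cts
(`merge_runs()`), the simplest consolidation consistent with reporting
one ranking per study.

A mask of (group, region) pairs flags cells excluded from stability
ranking while staying available to quantification — the treatment needed
when one group's cDNA was primed differently (oligo-dT) and its CDS
amplicons are therefore biased.  All pairwise statistics are computed
pairwise-complete over unmasked samples, requiring at least 2 shared
samples per pair; regions with fewer than 2 usable samples are dropped
with a warning.  The pipeline applies the configured mask to all three
estimators uniformly; we prefer one consistent exclusion rule over
method-specific ones, and note it where per-group tables are compared.

## The synthetic generator

`simulate_qpcr()` draws
`Ct = base + group_shift + loading(sample) + gene_noise + rt_bias +
sample_shift + well_noise`, all additive on the cycle scale — i.e.
log-multiplicative on quantities, matching how qPCR error behaves and
what the estimators assume.  `preset_study_like()` fixes the study-like
conditions used throughout the tests: 4 groups of 4/6/4/2 samples,
17 regions over 8 genes with base Cts spanning ~21–29 cycles,
efficiencies spread over 0.91–1.12, loading SD 0.8 cycles, well SD 0.1
cycles, three wells per cell, a +1 cycle bias on CDS regions in the
oligo-dT group (halving apparent CDS template, with those cells
pre-masked), and gene noise SDs from 0.10 (best: `HIS_cds`, `SAND_utr`,
`TIP_utr`) to 0.55 cycles.  The three least stable regions additionally
carry about one cycle of group-to-group expression shift, reflecting how
strongly group-divergent the worst candidates are in real validation
panels; CDS/UTR base-Ct gaps are kept within a cycle of each other, as
observed for same-gene amplicons.  The optional targets are two
cold-inducible genes with a mid-winter expression peak in flower buds
and near-absent expression in fruit.

What the generator does *not* emulate: amplification-curve shape,
inhibitor-driven efficiency variation between samples, melting-curve
behaviour, inter-run batch effects, or any sequence-level process.
Passing tests therefore demonstrate correctness of the estimators and
pipeline under the stated error model, not robustness to instrument
artefacts outside it.

## Numerical and design choices

- SDs use the n−1 denominator everywhere; logs are base 2 (any fixed
  base gives identical rankings; reported values follow the log2
  definitions).
- Stability statistics are invariant to per-sample scaling by
  construction; tests assert this exactly (1e−12), as well as oracle
  equivalence of M, `V_n/n+1`, ΔCt SDs and the variance decomposition
  against independent brute-force implementations.
- Degenerate inputs: proportional regions give M = V = 0; identical
  columns rank tied; a region exactly tracking the sample effect scores
  ρ = 0; an all-constant matrix yields `V_n/n+1 = 0` and `sufficient_n
  = 2`.
- The post-normalization CV reported for a reference set divides each
  member by the set's own NF and takes SD/mean across samples — a direct
  measure of residual variation of the chosen references after
  normalization.  Other CV definitions exist; this one is computed from
  quantities the pipeline already has and is documented here to avoid
  ambiguity.
- Per-group analyses subset samples but reuse the global standard
  curves: a curve characterizes an amplicon, not a sample group.
- Reports (`write_report()`) contain no timestamps, so identical inputs
  and seed give byte-identical files.

Test problem sizes: oracle checks use 50 random 6-region × 10-sample
matrices; recovery checks use 100 seeded simulations of the 16 × 17
preset; the script `scripts/acceptance.R` uses 50 and 30 seeds for its
two recovery rates.  These sizes give comfortable stability of the
reported rates while keeping a full run in tens of seconds.

## Limitations

- The ΔCt screen inherits its known efficiency blindness; discordance
  between ΔCt and the curve-based rankings on real data often traces to
  exactly that.
- The model-based estimator assumes independent gene noise after
  removing sample effects; co-regulated candidates (e.g. two amplicons
  of one transcript) violate this and should be thinned with the
  homologue pre-filter first.
- `V_n/n+1` with few samples is itself noisy; the 0.15 cutoff is a
  convention, not a test with error control.
- No vendor instrument exports are parsed; users provide long-format
  CSVs.

## A complete run

```{r example, eval = FALSE}
spec <- preset_study_like()
sim  <- simulate_qpcr(spec, seed = 1)
report <- run_screening_pipeline(sim$ct, sim$dilutions, study_config(keep = 6))
report
summary(report$rankings$genorm$overall)
write_report(report, "refstab-run")
```
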