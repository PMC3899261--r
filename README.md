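# refstab

Reference-gene stability evaluation and normalization for RT-qPCR.

Relative quantification by RT-qPCR stands or falls with the reference
("housekeeping") genes used to normalize it: a gene whose own expression
drifts across tissues, treatments or seasons silently distorts every
target-gene estimate.  `refstab` implements the standard validation
workflow for choosing references from a panel of candidate amplicons:

- **Quantification.** Threshold cycles (Ct) are converted to relative
  quantities through dilution-series standard curves,
  `Ct = b + m · log10(Q)`, with amplification efficiency
  `E = 10^(−1/m) − 1`.  Initial template amounts for two amplicons of the
  same gene are compared as `Q0 = T/(1+E)^Ct` (fluorescence threshold
  `T`), a diagnostic for multi-locus CDS amplification and for template
  depletion under oligo-dT reverse-transcription priming.
- **geNorm.** For genes *j*, *k* the pairwise variation
  `V_jk = SD( log2 q_j/q_k )`; the stability value `M_j = mean_k V_jk`.
  The gene with the highest M is removed and M recomputed until three
  genes remain.  The normalization factor `NF_n` is the geometric mean of
  the *n* best genes per sample, and `V_n/n+1 = SD( log2 NF_n/NF_{n+1} )`
  decides how many references suffice (cutoff 0.15).
- **NormFinder-style model-based ranking.** Log quantities are decomposed
  into per-sample effects, group-by-gene deviations `d` and gene-specific
  residual variance `σ²` (bias-corrected, with `d` shrunk toward 0); the
  stability value combines `|d|` with the gene's total error variance,
  overall or within single groups, and identifies the best two-gene
  combination via deviation cancellation.
- **ΔCt screen.** Genes ranked by the mean SD of pairwise Ct differences —
  no standard curves needed, making it the recommended cheap first pass
  before geNorm/NormFinder on the shortlist.
- **Synthetic data.** A generator with known ground truth (gene noise,
  group shifts, per-sample loading, dilution series, RT-primer bias) so
  the whole pipeline is testable end to end.

## Worked example

```r
library(refstab)

spec <- preset_study_like()          # 16 samples, 4 tissue groups, 17 regions
sim  <- simulate_qpcr(spec, seed = 1)
sim$ct
#> <ct_table> 816 wells | 16 samples in 4 groups | 17 regions
#>   mask: FB/HIS_cds, FB/EF1a_cds, FB/ANX_cds

report <- run_screening_pipeline(sim$ct, sim$dilutions, study_config(keep = 6))
report
#> <refgene_report>
#>   stage 1 kept: EF1a_cds, HIS_cds, TIP_utr, SAND_utr, HIS_utr1, EF1a_utr1
#>   geNorm trio: EF1a_cds, HIS_cds, HIS_utr1 (trio M = 0.126)
#>   NormFinder best: EF1a_cds (0.035); best pair: EF1a_cds + HIS_cds (0.037)
#>   NF references: HIS_cds, EF1a_cds, HIS_utr1 | V = 0.043 -> 3 genes sufficient
#>   mean CV of normalized references: 0.169
```

The ΔCt screen kept the six candidates with the smallest mean pairwise-ΔCt
SD; geNorm's stepwise elimination retained a trio with average M = 0.126
(log2 units — well under the usual ≤ 0.5 comfort zone), and
`V_3/4 = 0.043 < 0.15` confirms that three references are enough.  The
reported CV is the residual coefficient of variation of each reference
after dividing by the trio's geometric-mean normalization factor.

Individual pieces are available directly:

```r
fit_standard_curves(sim$dilutions)[["SAND_utr"]]
#> <standard_curve> SAND_utr slope -3.1020, intercept 24.962, E = 110.1%, r2 = 0.9998 (5 points)

template_ratio(sim$ct, "HIS_cds", "HIS_utr1", sim$truth$efficiency)
#> <template_ratio> HIS_cds / HIS_utr1 (Rn threshold 0.30)
#>   overall: 1.308 +/- 0.373 (n = 16)
#>   FB: 0.720 +/- 0.128 (n = 4)
#>   ...
```

The CDS/UTR template ratio sits above 1 in most groups (the CDS primers
see several homologous loci) but drops below 1 in the flower-bud group,
whose cDNA the generator synthesizes with the oligo-dT primer bias — the
reason those cells are masked from stability ranking.

Real data enter through `read_ct_table()` (long-format CSV: sample,
group, region, replicate, Ct, with a configurable "Undetermined" token)
and `read_dilution_series()`; `normalize_target()`,
`robustness_compare()` and `write_report()` cover target-gene
normalization and reporting.

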