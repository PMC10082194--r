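# hrdkit

Genomic scars of homologous-recombination deficiency (HRD) predict whether a
triple-negative breast cancer responds to platinum chemotherapy, and
patient-derived xenografts (PDX) are the preclinical setting in which that
prediction can be tested against a measured drug response. `hrdkit`
implements the complete computational chain for such a study, for
bioinformaticians and preclinical pharmacologists:

- **Shallow-WGS HRD calling.** From a binned copy-ratio profile (e.g. 50 kb
  QDNAseq-style bins): per-chromosome penalized least-squares change-point
  segmentation, estimation of the per-profile minimal copy-number-alteration
  cutoff (first valley of the density of inter-level differences), iterative
  segment merging, and counting of **large-scale genomic alterations**
  (LGA): breaks between adjacent (< 3 Mb apart) same-arm segments each
  > 10 Mb whose levels differ by at least the cutoff. Samples with
  > 20 LGAs are called HRD, < 18 HRP, 18–20 borderline (flagged for manual
  review, never auto-resolved).
- **Allele-specific scar scores.** From integer allele-specific copy-number
  segments: **LOH** (loss-of-heterozygosity regions ≥ 15 Mb but less than a
  whole chromosome), **TAI** (telomeric allelic imbalance, arms whose
  telomere-anchored imbalanced run exceeds 500 probes with a balanced
  centromeric segment), **LST** (large-scale state transitions between
  adjacent ≥ 10 Mb segments after 3 Mb smoothing), and their sum.
- **PDX response metrics.** Tumour volume `V = a·b²/2`; per-mouse percent
  volume change ΔVol_t = 100·(V_t − V0)/V0; **BestResponse** = min ΔVol_t
  and **BestAvgResponse** = min running mean of ΔVol over t ≥ 14 d; per-model
  medians classified CR / PR / SD / PD by the ordered strict rules
  (CR: < −95 and < −40; PR: < −50 and < −20; SD: < 35 and < 30; else PD).
- **RAD51 functional scoring.** Percent of marker-positive cells with > 5
  RAD51 foci; a PDX whose treated-arm mean is < 10% is functionally
  HR-deficient.
- **Variant filtering.** The whole-exome somatic filter cascade (depth,
  frequency, clinical significance, functional class, cohort recurrence,
  population frequencies, effect-predictor votes), the targeted-panel
  profile, gene-list restriction (cancer-census / DNA-damage-response), and
  LOH inference from variant allele frequency.
- **Fusion-derived deletions.** Median-of-ratios count normalization, then
  intra-chromosomal fusions whose spanned region is expression-depleted
  (region sum and every contained gene at or below the 10th percentile).
- **Biomarker statistics.** Exact two-sided Fisher tests by direct
  enumeration, diagnostic metrics, Pearson correlation, exact Mann–Whitney,
  Kaplan–Meier with the Gehan–Breslow–Wilcoxon test.
- **A fully seeded synthetic-cohort generator** producing every input above
  with recorded ground truth (planted LGA breaks, scar events, response
  trajectories, foci mixtures, single-rule variant violations, planted
  expression deletions), so the whole pipeline is testable end to end.

## Worked example

```r
library(hrdkit)
genome <- load_genome("toy3")

# plant 25 qualifying arm breaks, add bin noise, and call LGAs back
sim <- simulate_binned_profile(25, genome = genome, noise_sd = 0.05, seed = 7)
seg <- segment_profile(sim$profile)
cut <- estimate_level_cutoff(seg)
call_lgas(merge_segments(seg, cut), genome, cut)
#> <lga_report> sample sim: 25 LGAs -> HRD
#>   arms: 1p=4 2p=4 3p=4 1q=4 2q=4 3q=5

# scar scores from a planted allele-specific profile
scars <- simulate_allelic_profile(3, 2, 4, genome = genome, seed = 3)
hrd_scar_score(scars$profile, genome)
#> <scar_scores> sample sim: LOH=3 TAI=2 LST=4 total=9

# the response metrics of a shrinking tumour measured on days 0/7/14/21
s <- delta_vol_series(data.frame(mouse = "m1", day = c(0, 7, 14, 21),
                                 volume = c(100, 70, 40, 20)))
c(best = best_response(s), best_avg = best_avg_response(s))
#>     best best_avg
#>    -80.0    -42.5
classify_response(-80, -42.5)
#> [1] "PR"

# a whole simulated cohort, scored end to end
report <- run_pipeline(list(seed = 11))
report
#> <run_report> 55 PDX models
#>   HRD vs response Fisher p = 0.0151
#>   LGA ~ scar-score Pearson r = 0.908
```

The 25 planted breaks are recovered exactly despite the bin noise; the
trajectory worked by hand gives BestResponse −80%, BestAvgResponse −42.5%
(the minimum of the running means −30 and −42.5), a partial response. On the
default simulated cohort the genomic HRD call is strongly associated with
platinum response and the two HRD scores correlate at r ≈ 0.91.

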