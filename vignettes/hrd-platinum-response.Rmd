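---
title: "Scoring homologous-recombination deficiency and platinum response in PDX cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring homologous-recombination deficiency and platinum response in PDX cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrdkit)
```

Tumours that cannot repair double-strand breaks by homologous recombination
(HR) accumulate characteristic genomic scars and are preferentially killed
by platinum salts. `hrdkit` implements the computational machinery for
studying that link in patient-derived xenografts (PDX): genomic HRD scoring
from copy-number data, functional HR scoring from RAD51 foci, tumour-volume
response metrics, the supporting variant and fusion screens, and the
association statistics. This vignette explains the models, the parameters
that matter, and the design decisions behind the implementation.

## LGA-based HRD calling from binned copy-ratio profiles

The shallow-WGS HRD statistic counts **large-scale genomic alterations**:
copy-number breaks between adjacent segments, each longer than 10 Mb, lying
on the same chromosome arm less than 3 Mb apart, with a level difference at
least the per-profile cutoff. The pipeline is:

1. **Segmentation** (`segment_profile`). Per chromosome, a piecewise-constant
   least-squares fit with a fixed penalty per breakpoint, solved exactly by
   penalized optimal partitioning with PELT pruning. The default penalty is
   $2\hat\sigma^2\log n$ with $\hat\sigma$ the robust noise scale from lag-1
   bin differences (MAD/$\sqrt2$) — a BIC-like choice we calibrated on
   synthetic step profiles; it recovers planted breakpoints within ±2 bins
   at noise equal to 10% of the level step. Chromosome boundaries are always
   breakpoints. The method is deterministic and is checked in the tests
   against an exhaustive dynamic program on small inputs.
2. **Minimal-CNA cutoff** (`estimate_level_cutoff`). Real copy-number steps
   in a profile form discrete clusters in the distribution of pairwise
   level differences among large (≥ 10 Mb) segments, while noise
   differences cluster near zero. The cutoff is the location of the first
   local minimum of a kernel density estimate of those differences — the
   valley separating noise from the smallest real alteration. On profiles
   with no level structure the fallback is $3\times$ the median absolute
   deviation of within-segment bin residuals. The valley rule follows the
   published shallow-HRD method in spirit; its constants (density grid,
   10 Mb size floor, MAD multiplier) are this package's own.
3. **Merging** (`merge_segments`). Adjacent same-chromosome segments are
   merged smallest-difference-first while the difference is below the
   cutoff, the merged level being the bin-weighted mean. Merging recomputes
   differences after every step, so the result is a fixed point: no
   remaining adjacent pair differs by less than the cutoff.
4. **Counting and classification** (`call_lgas`, `classify_hrd`). Segments
   are split by arm (the centromere interval is excised and belongs to no
   arm; gaps across it therefore exceed the 3 Mb rule, so breaks never span
   the centromere), arm segments strictly longer than 10 Mb are retained,
   and qualifying junctions are counted. Totals above 20 are HRD, below 18
   HRP, and 18–20 is reported as *borderline* — the classification the
   original procedure resolves by manual review of ploidy and profile
   quality, which we deliberately do not automate; the report carries a
   free-text review flag instead.

Size rules are applied strictly ("more than 10 Mb", "less than 3 Mb") as
printed. A level difference must also reach the cutoff to count as a break;
without that requirement every retained-segment junction would count and
the statistic would saturate. The linear copy ratio is the internal unit
throughout; the profile reader accepts a `scale` flag and converts log2
input on ingest.

## Allele-specific scar scores

`hrd_scar_score` smooths the profile once (alterations under 3 Mb are
removed and like-state neighbours fused) and computes three components on
the same smoothed profile:

- **LOH**: maximal runs of segments with minor copy number zero
  (contiguous when gaps are under 3 Mb), counted when spanning at least
  15 Mb but not the chromosome's whole assayed extent. The definition is
  chromosome-level — runs may cross the centromere — because, unlike TAI
  and LST, it is phrased per chromosome; we note this as an
  interpretation. Copy-neutral and deletion LOH are not distinguished: the
  criterion constrains only the minor allele.
- **TAI**: an arm scores when the imbalanced run anchored at its telomeric
  end (the run containing the outermost assayed segment) sums to more than
  500 probes while the arm segment nearest the centromere is balanced
  (major = minor, exact on integer input). The 500-probe criterion is kept
  in probe units because the assay it comes from is array-based; a
  size-based alternative is available through the probe-density of the
  input.
- **LST**: state changes between consecutive retained (≥ 10 Mb) arm
  segments separated by less than the 3 Mb smoothing size.

Balance is exact equality of integer major/minor copy numbers — the input
is discretized upstream, so no tolerance is needed. No HRD threshold is
applied to the total: the score is used for correlation and
sensitivity/specificity analyses, and any cutoff is the user's.

## Tumour-volume response metrics

Volumes come from perpendicular caliper diameters as $V = ab^2/2$.
Per mouse, $\Delta\mathrm{Vol}_t = 100\,(V_t - V_0)/V_0$. **BestResponse**
is the minimum of $\Delta\mathrm{Vol}_t$ over measured days $t \ge 14$;
**BestAvgResponse** is the minimum over $t \ge 14$ of the unweighted mean
of $\Delta\mathrm{Vol}$ over all measured days from 0 to $t$ inclusive.
Two readings deserve a note. First, the day-0 value (0 by definition) is
included in the running mean, following the "from $t=0$ to $t$" phrasing;
`include_t0 = FALSE` provides the sensitivity analysis. Second, the
formula's "final volume" is read as the per-timepoint series
$\Delta\mathrm{Vol}_t$ (the reading consistent with minimizing over time),
not a single end-of-treatment value. Classification applies the ordered
strict rules CR → PR → SD, else PD; medians over evaluable mice (those
with any day ≥ 14 measurement; mice sacrificed earlier at the 2000 mm³
ethical limit are excluded and counted) are classified with the same
rules. Measurement days need not align across mice and nothing is
interpolated.

## RAD51, variant filters, fusions

A cell is RAD51-positive with strictly more than 5 foci; a PDX is
functionally HR-deficient when the unweighted mean percent-positive across
treated xenografts is strictly below 10%. The source protocol states the
deficiency rule once in a form that contradicts its own positivity
definition ("less than 5 foci in less than 10% of cells"); we implement
the reading consistent with the positivity definition and the result
figures — percent of cells with *more than 5* foci below 10% — and expose
`inclusive = TRUE` for the "5 or more" variant, which the source also uses
in one place. Both thresholds are parameters.

The exome filter cascade records, per variant, every rule it fails:
alternative depth < 2, alternative frequency < 0.25, benign clinical
significance, synonymous SNV, non-exonic/splicing class, presence in ≥ 5
distinct tumours, any population-database frequency > 0.001, and more than
2 of 5 effect predictors voting a benign-leaning label (missing predictions
are never votes). The printed depth/frequency rule is conjunctive if read
literally, which would keep depth-1 variants at high frequency; the default
applies the two minima independently, with `rule1_conjunctive = TRUE` for
the literal reading. The targeted-panel rule has a similar ambiguity
("low frequency or low coverage and high population frequency"); the
default is disjunctive (any condition rejects), with
`conjunctive_popfreq = TRUE` for the literal grouping. LOH of BRCA1/2 is
inferred when the variant allele frequency reaches 0.7 (inclusive) — a
default of this package, not of the source, and tunable for purity.

Fusion-derived deletions: same-chromosome fusion calls span a candidate
region; candidates touching the DNA-damage-response list are tested against
median-of-ratios-normalized expression. The verdict requires the candidate
sample's summed region count at or below the 10th percentile of that region
sum across **all** samples, and every region gene at or below the gene's
10th percentile across the **other** samples — each clause read literally
from its own phrasing; both reference populations are configurable. The
percentile is the inclusive linear-interpolation quantile, fixed for
reproducibility. Size factors use the log-space median of count/geometric-
mean ratios, matching DESeq2's estimator to numerical precision (a test
cross-checks this when DESeq2 is installed).

## Association statistics

The two-sided Fisher exact p-value is computed by direct enumeration over
the feasible cell range with probability-mass ordering (tables no more
probable than the observed one, relative tie tolerance $10^{-7}$) — the
convention of standard statistical software; the suite verifies equality
with exhaustive enumeration for every 2×2 table up to N = 60. The response
grouping of a contingency analysis (CR+PR+SD vs PD, CR+PR vs rest) is
always an explicit argument. Diagnostic metrics use the standard
column-conditional definitions, with undefined denominators reported as
`NA`. Mann–Whitney is exact (via the null rank-sum distribution) for
min(n, m) ≤ 10 without ties, otherwise normal with tie and continuity
corrections. Survival comparison uses the product-limit estimator, the
KM-based median (first time the curve reaches 0.5), and the
Gehan–Breslow–Wilcoxon statistic: the log-rank family with the number at
risk as weight, on 1 df. Methylation banding (≥ 90 complete, 40–60
partial, < 10 unmethylated) encodes observed ranges, not validated
cutoffs; out-of-band values class as partial with a warning, and all
boundaries are parameters.

## The synthetic cohort: what it does and does not emulate

The generator (`cohort_spec`, `simulate_cohort` and the per-table
functions) produces every pipeline input with recorded ground truth. Its
defaults are the package's study conditions, chosen once:

- 55 models, HRD prevalence 30/55; response probabilities per state
  (HRD: CR/PR/SD/PD = 0.30/0.17/0.23/0.30; HRP: 0.04/0/0.28/0.68),
  reproducing in expectation the reference cohort's marginals
  (≈ 10/5/14/26 with 21 of 29 responders HRD).
- LGA totals: HRD = 21 + Poisson(9) (mean 30), HRP = Poisson(8) capped at
  17 — clear of the 18–20 borderline window so planted truth has an
  unambiguous class.
- Profiles: 50 kb bins on the bundled 3×200 Mb toy genome, planted
  qualifying breaks with a 0.5 level step and Gaussian bin noise
  (default sd 0.05, i.e. 10% of the step). Scar events are placed on
  distinct arms so each scores exactly once; per-model scar rates are the
  state rates scaled by the model's LGA severity, making the two HRD
  scores share one latent state, and are sized to the toy genome (about a
  fifth of a human genome, hence totals about a fifth of clinical scar
  scores).
- Growth: day 0–42, twice-weekly measurements, 8 mice per arm, V0 uniform
  on 60–200 mm³; treated trajectories are exponential-family curves per
  intended category (CR decays below 5% of V0 by day 14; PR plateaus near
  25%; SD drifts to 90%; PD grows at 6%/day), controls grow exponentially
  with lognormal rate spread; multiplicative lognormal measurement noise;
  measurements stop once 2000 mm³ is reached. The growth model is a test
  harness, not a fitted tumour-growth model.
- Foci: treated-arm per-cell counts Poisson(1) for HR-deficient models and
  Poisson(9) for proficient ones, 200 cells per sample — separations under
  which the 10% rule recovers the planted state in ≥ 99% of replicates.
- Variants violate exactly one named rule each; one expression sample
  carries a 100-fold depleted gene block with its matching
  intra-chromosomal fusion.

All randomness flows from one root seed through named substreams, so any
table can be regenerated independently and identical seeds give identical
bytes. What passing tests on these data show is that the *scoring chain*
is correct: planted events are recovered, filters reject for the planted
reasons, the association statistics are calibrated (the null-cohort Fisher
rejection rate stays under its nominal level). What they cannot show is
robustness to the failure modes of real data — ploidy shifts and
subclonality in copy-number profiles, wavy GC artefacts, stromal and mouse
contamination, array probe-density variation, segmentation over dense
real breakpoint landscapes — none of which the generator models.

## Numerical choices and limitations

- Coordinates are 0-based half-open internally; on-disk tables are 1-based
  inclusive and converted at the reader/writer boundary.
- Exact optimal partitioning is used for segmentation throughout the sizes
  this package targets (thousands of bins per chromosome); the PELT
  pruning keeps it near-linear on profiles with many changes.
- Problem sizes in the test suite and acceptance script (hundreds of
  simulated profiles, 500 label-level cohorts, exhaustive Fisher
  enumeration to N = 60) were chosen to exercise every claim while keeping
  a full run in minutes on one core.
- The manual re-scoring of individual borderline or tetraploid study
  samples is out of scope by design: no published rule exists, so the
  report flags rather than resolves such cases.
- The bundled cancer-census list is a synthetic placeholder subset and the
  DDR list a curated process-based compilation; both are plain text and
  meant to be replaced by the user's licensed or project-specific lists.
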