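---
title: "Evaluating blood-based DNA methylation age clocks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating blood-based DNA methylation age clocks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(pyroage)
```

## The problem

DNA methylation at a small number of CpG sites drifts with age in a way
that is consistent enough across individuals to support *epigenetic
clocks*: formulas that map percent methylation, measured by bisulfite
pyrosequencing in blood DNA, to a predicted chronological age. Such clocks
are attractive in forensics (age estimation from a blood trace) and in
epidemiology. Several blood-based pyrosequencing clocks have been
published, each trained in a different laboratory on a different cohort,
and a laboratory adopting one needs tooling to (i) apply the published
formulas exactly as printed, (ii) score them on its own cohort with the
standard accuracy statistics, and (iii) calibrate its pyrosequencing
assays against DNA standards of known methylation so that technical bias
is not mistaken for model failure. `pyroage` packages those three steps,
together with a synthetic-cohort generator that makes the whole pipeline
testable without access to any donor data.

## The clocks

Six clocks are built in (`builtin_models()`), spanning 16 distinct CpGs in
10 genes out of a 52-CpG, 11-gene pyrosequencing panel (`cpg_panel()`).
Each clock has the form

$$\hat{a} = \beta_0 + \sum_j \beta_j \, m_j^{e_j},$$

where $m_j$ is percent methylation (0–100) at CpG $j$ and $e_j = 1$ except
for one quadratic term: the Bekaert clock squares its `ELOVL2` CpG 6
value. Coefficients are stored at full published precision and applied to
unrounded methylation values; output is raw formula output in years — not
clamped to the training age range and not rounded (rounding belongs to
reporting, and `round_half_up()` is provided for table-style rounding).

Two encoding decisions deserve a note:

* **The Weidner formula** circulates in a typographically garbled form in
  which the gene names and parenthesised CpG indices are interleaved
  incorrectly. It is encoded here as
  $38.0 - 0.264\,\mathrm{ASPA}_1 - 0.237\,\mathrm{ITGA2B}_2 +
  1.647\,\mathrm{PDE4C}_1$, the reading consistent with the printed
  coefficient-to-gene order and with the clock's known CpG assignment.
* **Input scale.** The coefficient magnitudes imply percent (0–100)
  inputs. A matrix whose maximum value is at or below 1 is almost
  certainly on the beta (0–1) scale, and the API rejects it with an
  explicit error instead of silently producing nonsense ages.

Samples missing a required CpG are excluded from that clock (never
imputed) with the reason recorded; the other clocks still apply.

## Accuracy statistics

For each clock and stratum (all donors, men, women, and age groups I
19–34, II 35–49, III 50–65 — boundaries follow the cohort definition, an
age of exactly 35 falls in group II and is flagged on ingestion), the
evaluation reports:

* **Pearson r** and $R^2 = r^2$ between predicted and chronological age;
* **MAD**, the mean absolute deviation
  $\tfrac1n\sum_i |\hat a_i - a_i|$, in years;
* **SEE**, the standard error of the estimate
  $\sqrt{\sum_i (\hat a_i - a_i)^2 / n}$. The denominator is $n$ by
  default (the RMSE form): the clocks are applied *out of sample*, so no
  degrees of freedom are consumed by fitting. The regression convention
  $n-2$ is available via `eval_config(see_denominator = "n_minus_2")`;
  at $n = 100$ the two differ by a factor $\sqrt{100/98} \approx 1.01$.
  For any data $\mathrm{MAD} \le \mathrm{SEE}(n)$;
* **PCP**, the percentage of correct predictions at error thresholds of
  5, 7.5 and 10 years, with an *inclusive* boundary
  ($|\hat a - a| \le$ threshold);
* mean and median signed error (predicted − chronological), the
  over/under-estimation summary.

Between-stratum differences in signed error are tested with two-sided
pooled-variance Student t-tests (`group_difference_stats()`), reported
raw; a Bonferroni column is optional because the underlying analyses in
this field conventionally report unadjusted p-values. Strata with fewer
than `min_n = 3` usable samples keep their error metrics but report no
correlation.

## Assay calibration against methylation standards

Pyrosequencing assays are run on control DNA at 0/25/50/75/100%
methylation. PCR can preferentially amplify one allele; the signature of a
bias toward the unmethylated allele is intermediate standards reading far
below their nominal level while 0% and 100% stay close to expected. For
that reason `assess_standards()` classifies bias from the mean deviation
over the intermediate levels (25/50/75) only, with two config-exposed
cut-offs chosen as defaults here: 5 percentage points separates `none`
from `slight`, 20 points separates `slight` from `strong` (the published
description of these assays is qualitative, so the cut-offs are design
choices of this package, not published constants). The least-squares line
of observed on expected is reported alongside, and recovery of a perfectly
linear biased assay is exact to numerical precision. No correction is
applied to cohort data from the calibration curve — the analysis reports
bias, it does not adjust for it.

`compare_cycle_replicates()` performs the paired t-test across CpGs for
two amplification conditions (e.g. 45 vs 50 PCR cycles). When every
per-CpG difference is identical the paired t statistic is undefined; the
result is flagged `degenerate` with the limiting p-value (1 for zero
shift, 0 otherwise) rather than an error, since a constant shift is a
meaningful observation.

`duplicate_average_analysis()` quantifies the benefit of measuring
methylation twice: predictions from each replicate and from the
element-wise mean of duplicates are evaluated side by side. Averaging
independent measurement noise divides its variance by 2, so the
mean-of-duplicates run is expected to win; with two identical replicates
all three evaluations coincide exactly.

## The synthetic-cohort generator

The generator emulates the study conditions of a 100-donor blood cohort:
three age groups of 34/33/33 donors drawn uniformly over integer ages
19–34, 35–49 and 50–65, and a 42 F / 58 M gender split assigned by random
permutation (`cohort_design()`, `sample_cohort_meta()`). Methylation for
each CpG is linear in age with independent homoscedastic Gaussian noise,
clamped to [0, 100]:

$$m_{ij} = \mathrm{clamp}(a_j + b_j \, \mathrm{age}_i + \varepsilon_{ij},\ 0,\ 100),
\qquad \varepsilon_{ij} \sim N(0, \sigma_j^2).$$

Rather than asking the user for noise levels, $\sigma_j$ is derived from a
*target correlation*: for this linear model the population correlation
with age is $r = b\,s_a / \sqrt{b^2 s_a^2 + \sigma^2}$, so
`noise_for_target_r()` inverts it as
$\sigma = |b|\, s_a \sqrt{1/r^2 - 1}$, with $s_a$ the empirical age sd of
the cohort being generated. The bundled defaults
(`default_cpg_params()`) target the reference per-CpG age correlations of
the panel (e.g. 0.862 for `ELOVL2` CpG 6, −0.341 for `ITGA2B` CpG 2), so a
default synthetic cohort reproduces the panel's correlation *structure*:
mean |r| ≈ 0.64 over all 52 CpGs, with `ELOVL2` strongest.

Default trajectories are a deliberate compromise: slope
$b_j = 0.45\,r_j$ %/year and intercept anchored at 50% at age 42 keep
noise-free values within roughly [29, 71] over ages 19–65 and the derived
$\sigma_j$ below ~6 points, so clamping is negligible (clamp events are
counted and warned about, because heavy clamping would drag empirical
correlations below target). Ages are integers because donor ages are
recorded in whole years, and uniform within groups because only the group
totals are part of the emulated design. An optional `drift` argument adds
linear heteroscedasticity (noise sd growing with age, the epigenetic-drift
pattern); it is off by default.

What the generator does **not** emulate — and therefore what passing tests
do *not* establish about real data: absolute methylation levels per CpG
(the defaults are centred placeholders, not measured means, so clock
predictions on a default synthetic cohort are offset by construction and
only their *correlations* with age are meaningful), CpG–CpG residual
correlation within an amplicon, non-linear age trajectories, and
measurement error structure specific to pyrosequencing chemistry.

### Model-faithful cohorts

To test the prediction-evaluation machinery end to end we need cohorts on
which a clock *should* predict well. `model_faithful_params()` constructs
them: one required CpG (the *anchor*) gets its trajectory solved so that
the clock, applied to the noise-free generator, returns exactly the
chronological age at two anchor ages (default 25 and 60). For the five
linear clocks the prediction is then affine in age, so it is exact at
*every* age; for Bekaert the quadratic `ELOVL2` CpG 6 term is solved by
root selection in [0, 100] at each anchor age and interpolated linearly
in between, leaving a bounded interpolation error (MAD ≈ 0.3 years over
ages 19–65 with the default base trajectories). Per-model default base
trajectories are chosen so the anchor solution stays inside [0, 100] —
with flat mid-range covariates the `KLF14` term of the Thong clock or the
quadratic argument of Bekaert would leave the feasible range, so those
models get low-lying covariate trajectories. Noise placed on the anchor
(`anchor_noise_sd`) feeds through the clock coefficients into prediction
error in a controlled, monotone way, which is what the pipeline-closure
tests exercise.

## Numerical choices

* Methylation values are never rounded on ingestion; reports are written
  at full precision and CSV/JSON round trips are bit-exact (report CSVs
  are re-parsed with R's own correctly-rounded string-to-double
  conversion).
* Pearson correlations require ≥ 3 complete pairs and non-constant
  vectors; a constant CpG column in the correlation table yields a row
  flagged `undefined` rather than an error.
* Degenerate t-tests (zero-variance errors or differences) return the
  limiting values (t = 0, p = 1 for no shift) with a `degenerate` flag.
* All generators take explicit integer seeds and restore the caller's RNG
  state; identical seeds give identical outputs.
* `run_full_analysis()` stages its outputs in a temporary directory and
  moves them into place, so a failed run leaves no partial tables. The
  manifest records seed, versions, an MD5 of the input file, and all
  exclusion/warning counts.

## Problem sizes used in the automated checks

The test-suite and acceptance-script simulations use the 100-donor design
for pipeline checks, n = 5 000 cohorts for correlation-recovery checks
(sampling error of $\hat r$ at that size is ~0.013 for the weakest panel
CpG, comfortably inside the ±0.03 acceptance band), 200 simulated
duplicate pairs at noise sd 3 for the duplicate-averaging property, and 50
seeds per noise level for the noise-monotonicity property. These sizes are
the package's chosen compromise between statistical resolution and the
few-minutes runtime appropriate for a routine check.

## Known limitations

* The six clocks are applied as published; no refitting, recalibration,
  cell-composition correction or covariate adjustment is offered.
* Calibration findings are reported, not corrected for: a strongly biased
  assay (e.g. one that collapses intermediate standards toward 0) will
  still feed its measured values to the clocks.
* The xlsx cohort dialect reads a first-sheet, header-row workbook layout
  and maps headers like `ELOVL2 (CpG_6)` onto the native naming; workbook
  layouts beyond that need conversion to the native CSV format.
* Synthetic cohorts validate the *machinery*, not the clocks: agreement
  between a clock and synthetic data says nothing about its accuracy on
  real blood samples.
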