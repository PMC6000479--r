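---
title: "Regression-based norms and test-retest reliability: methods and design"
author: "acsnorms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regression-based norms and test-retest reliability: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Self-administered online cognitive batteries produce raw scores (completion
times, word counts, repeated sequences) whose interpretation depends
strongly on age, and to a lesser degree on gender and education.
Traditional norm tables stratify a reference sample into demographic cells;
with a few hundred volunteers this wastes information and produces jumpy
cell boundaries. Regression-based norming instead fits a continuous model
of the demographic expectation and expresses an individual's performance as
a standardized residual from it. This package implements that pipeline for
batteries shaped like the Amsterdam Cognition Scan (ACS): eleven outcome
measures plus a composite, two assessment occasions for reliability.

## Cleaning

Online self-administration produces artifacts — distraction, connection
glitches, a participant answering nothing — that look like extreme scores.
Two rules are applied, in a fixed order, before any analysis:

1. **Zero rule.** For count-based measures flagged `zero_is_invalid`
   (Wordlist Learning, Box Tapping, Digit Sequences I/II), a raw score of
   exactly 0 is excluded: a zero answer pattern reflects a usability
   failure rather than floor performance. Missing data are represented by
   row *absence* and are never confused with zeros.
2. **MAD rule.** For time-based measures (those with an inverse or log10
   transform: Connect the Dots I/II, Reaction Speed, Fill the Grid),
   limits `median ± m · c · MAD` are computed separately per age group
   (≤40, 41–59, ≥60 by default) and per occasion, with multiplier
   `m = 3.5`. Values strictly outside the limits are flagged; ties at a
   limit are retained (conservative exclusion).

Design choices a user should know about:

* **Consistency constant.** Whether the 3.5 multiplier applies to the raw
  MAD or to the normal-consistent scaled MAD (`c = 1.4826`) materially
  changes the limits. The default includes the constant, matching the
  standard MAD-outlier literature; `outlier_config(consistency_constant = 1)`
  switches it off, and the choice is echoed in the cleaning report.
* **Per-occasion limits.** Practice effects shift retest distributions, so
  pooling occasions would bias the limits; each occasion is cleaned
  against its own limits.
* **Raw scale.** Limits are computed on raw scores (seconds,
  milliseconds), not on transformed scores, because the rule is a screen
  for implausible observed values. A consequence worth stating plainly:
  completion-time distributions are genuinely right-skewed, so on clean
  Gaussian-latent data the rule still flags roughly 1.5–3% of time-measure
  rows in the far right tail. That matches what happens with real
  reference data (reference-study exclusion counts on these measures were
  of the same order) and is the price of a robust symmetric rule on a
  skewed scale.
* **Idempotence.** Re-running the cleaner on an already-cleaned table
  flags nothing new: the limits are recomputed on all rows not excluded
  for *other* reasons (manual exclusions and zero scores stay out, earlier
  MAD flags stay in). Without this convention each pass would shrink the
  MAD and cascade.
* **Degenerate groups.** Groups with fewer than 3 values, or with
  `MAD = 0` (half the group at one value), are skipped with a warning and
  nothing is flagged.

## Transforms, standardization, composite

Each measure carries a normalizing transform fused with its reverse
scoring, so the transformed scale is always "higher = better":

| transform | mapping | used for |
|---|---|---|
| inverse | `1/x` | Connect the Dots I, Reaction Speed, Fill the Grid |
| log10 | `−log10(x)` | Connect the Dots II |
| sqrt | `−√x` | Place the Beads (extra moves) |
| none | `x` (or `−x` if lower-is-better) | count measures |

For the inverse transform the reciprocal itself performs the reversal — no
additional sign flip — which is fixed bit-exactly by the published worked
example (`(1/60 − .0304)/.00793 = −1.73` for a slow 60 s completion). For
log10 and sqrt the reversal is expressed as a sign flip *of the transformed
value* (`−log10 x`, not `log10(−x)`); this keeps the transform monotone on
the raw domain and reproduces the negative age effects of the published
models.

Standardization constants (transformed-scale mean and SD) are always
computed from **occasion-1, non-excluded reference scores** and frozen into
the norm model: norm scoring of a new individual must never depend on the
cohort that individual arrives with. Both occasions are standardized with
the same frozen constants so practice shifts stay visible on the z scale.

The composite (total) score is the arithmetic mean of the nine composite
measures' z-scores, complete cases only — a participant missing any
component is counted out of composite analyses, not imputed. Wordlist
Recognition (ceiling effect, too little variance) and Place the Beads
(normed on a separate sample) stay out of the composite.

## Test-retest reliability

All reliability statistics are computed on raw scores, per measure, using
only participants non-excluded on **both** occasions for that measure.
From the two-way ANOVA mean squares (subjects × occasions):

* **ICC(A,1)** — two-way, absolute agreement, single measures:
  `(MS_R − MS_E) / (MS_R + (k−1)MS_E + (k/n)(MS_C − MS_E))`. The variant is
  fixed because only absolute agreement charges systematic occasion shifts
  (practice effects) to error; the consistency-type ICC would ignore them.
  If every score is identical the ratio is 0/0; agreement is then perfect
  by definition and 1 is returned with a warning.
* **SEM** `= √MS_residual`, in raw units.
* **SDC** `= 1.96 · √2 · SEM`; **group SDC**
  `= (SDC + |mean₁ − mean₂| · [practice]) / √n`. The practice-effect
  adjustment adds the occasion mean difference to the numerator *before*
  dividing — the only reading that reproduces the published group SDC
  values from their printed SEMs, n's and means.
* **Practice effect** — two-tailed paired *t* at α = .05. The flag is
  purely `p < .05`; the direction of the change is reported via the means
  but does not gate the flag (in the reference data every significant
  change was an improvement).
* **Retest correlation** — Pearson when Shapiro–Wilk (α = .05, each
  occasion, deterministically thinned to 5000 values for larger samples)
  rejects neither occasion, Spearman otherwise. The test is a package
  choice: "depends on the distribution" admits several operationalizations,
  so the method is configurable and always reported alongside the value.

## Demographic norm models

Standardized occasion-1 scores are regressed on centered age
(`age − age_center`), centered age squared, gender (0 = female, 1 = male)
and education (0 = high, Verhage 6–7; 1 = low/medium, Verhage 1–5), by
ordinary least squares. Centering age at the reference mean (49.19 years
for the shipped models) removes the collinearity between the linear and
quadratic terms. Predictors with *p* > .05 are pruned **in one pass** and
the model refitted once, matching the "exclude, then rerun" procedure;
`fit_config(iterative = TRUE)` switches to classical backward elimination.
Variance inflation factors above 10 abort the fit; Breusch–Pagan and
Shapiro–Wilk results are attached as advisory flags only, since for
parameter estimation heteroscedasticity and non-normal residuals do not
invalidate the coefficients.

A new individual's norm score is

```
z_actual    = (transform(raw) − ref_mean) / ref_sd
z_predicted = constant + Σ βⱼ xⱼ
norm        = (z_actual − z_predicted) / sd_residual
```

**Sign convention.** The published worked example prints the difference as
−1.34 from operands that arithmetically give +1.34 if read as "predicted −
actual"; the implemented convention is `actual − predicted`, which
reproduces both the printed −1.34 and the final norm score's sign, and
makes below-expectation performance negative. Canonical here.

**Rounding.** The worked example chains its *printed* two-decimal
intermediates: (−1.73 − (−0.39))/.819 = −1.64. The package computes at
full precision, which gives −1.6347 (→ −1.63 at two decimals) for the same
inputs. Both numbers are correct answers to slightly different questions;
the tests and the acceptance script reproduce the published chain
explicitly with rounded intermediates.

**Shipped models.** `acs_norm_models()` carries the published coefficients,
residual SDs, R² and n for all twelve measures. Transformed-scale
reference constants were published only for Connect the Dots I
(0.0304/0.00793), so only that model can produce norm scores out of the
box; all other shipped models are marked `NA` and norm scoring requires
user-fitted models (`fit_norm_models()`). The total-score model's
age-squared coefficient is 0.0 at the published precision although its
standardized effect (−.117) was significant; the shipped model stores the
published value.

## The synthetic cohort generator

No raw participant data are distributed with or required by the package;
`simulate_cohort()` generates cohorts with the structure the estimators
assume, which is exactly what makes recovery a fair test:

* demographics: age ~ Normal(49.2, 13²) truncated to 18–81 years, 63.3%
  female, 71% high education (the reference cohort's composition);
* latent standardized score per person and measure:
  `pred(demographics) + person + occasion noise`, with the published
  regression coefficients and residual SDs as generators;
* occasion-2 raw scores shifted by the observed practice effects
  (clamped at the measure's domain boundary — no negative extra moves);
* raw scores obtained by de-standardizing and inverting the measure's
  transform, with rejection of draws outside the transform domain;
* artifacts injected at configurable rates: zeros on count measures, and
  extreme values placed `outlier_displacement` (default 5) scaled MADs
  from the age group's median on time measures, all recorded in a ground
  truth registry.

**ICC calibration.** The split of the residual variance into a stable
person component and occasion noise is solved numerically (root-finding
over a common-random-number Monte Carlo of 2·10⁵ draws) so that the
*population* absolute-agreement ICC of the raw scores — after per-age-group
MAD cleaning for time measures, and including the systematic practice-shift
component — equals the per-measure target. Calibrating against the
cleaned-scale ICC matters: the inverse transform's heavy right tail would
otherwise dominate the moment-based ICC, and the analysis pipeline always
cleans before reliability. At n = 20,000 the pipeline recovers a 0.67
target to within 0.003. Infeasible targets (e.g. ICC 1.0 together with a
nonzero practice shift) are refused with the attainable bound.

**What the generator does not emulate**, and hence what passing tests do
not establish about real data: count measures are generated on a
continuous scale (real word counts are integers), Wordlist Recognition's
ceiling/discreteness is replaced by an intercept-only Gaussian, there is
no dropout process, no device or hardware effect, no within-session
dependence between measures beyond shared demographics, and the
transformed-scale reference constants for all measures except Connect the
Dots I are synthetic (delta-method values from the published raw means and
SDs), chosen once to land raw scores on a realistic scale.

## Numerical conventions and problem sizes

* Serialization: norm models and batteries are JSON with an explicit
  `schema_version`; round-trips are lossless at full double precision;
  unknown keys are ignored with a warning, version mismatches are errors.
* Seeds: a cohort is bit-identical given `seed`; the calibration draws
  come from the same stream.
* Degenerate inputs have defined behavior throughout: MAD = 0 (warn, no
  flags), zero variance of paired differences (practice test undefined,
  flag false), identical scores (ICC 1 with warning), zero variance on an
  occasion (correlation undefined).
* The validation suite uses cohort sizes chosen to keep Monte-Carlo error
  well inside the assertion tolerances: n = 5000 for coefficient recovery
  (every generating coefficient within 3 standard errors), n = 2000 for
  ICC recovery (±0.03), n = 250 — the reference-cohort size — for the
  self-consistency of norm scores over the training cohort (per-measure
  mean 0 ± 0.02, SD 1 ± 0.02, the OLS identity up to the n/(n−p)
  degrees-of-freedom correction).

## Known limitations

* Education enters as a binary code; the shipped models were fitted on a
  cohort with almost no low-education participants, so education effects
  are absent from most of them and extrapolation to low-education
  populations is unsupported.
* Norm models assume homoscedastic residuals across the demographic
  range when a single `sd_residual` scales the deviation; the advisory
  flags surface violations but the score formula does not model them.
* The composite's complete-case rule means its analysis sample is
  noticeably smaller than any component's.
* Published group-SDC values for a few measures (Fill the Grid, Reaction
  Speed, Digit Sequences I/II) cannot be reproduced exactly from their
  printed SEMs — consistent with unrounded internal values upstream — and
  are not used as exact checks.
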