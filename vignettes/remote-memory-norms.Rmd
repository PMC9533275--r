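---
title: "Regression-based norms for remotely administered verbal memory tests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regression-based norms for remotely administered verbal memory tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memnorms)
```

## The problem

Neuropsychological raw scores cannot be interpreted without norms, and norms
collected face to face do not automatically transfer to videoconference
administration. This package implements the full normative pipeline for five
verbal memory scores — Digit Span Forward and Backward (DSF/DSB, longest
span, 0–9), Rey Auditory Verbal Learning immediate and delayed recall
(RAVL-I 0–75, RAVL-D 0–15), and Verbal Paired Associates Learning (VPAL,
0–22.5 in half points) — as used for remote administration to healthy Italian
adults (ages 18–84, schooling 5–26 years), together with the simulation
machinery needed to compare two normative scoring systems on a patient
cohort.

The participant-level data behind the published norms are not available, so
the package ships (a) the five published adjustment equations and the
printed clinical correction grid as fixtures, and (b) a synthetic cohort
generator that reproduces the published sample *structure*, letting every
downstream stage be exercised and tested end to end.

## Demographic adjustment

For each test the raw score is regressed on transformed demographic
covariates and the fitted effects are removed:

1. **Transformation screening** (`screen_transforms()`): each candidate form
   is fit in a one-predictor least-squares regression and candidates are
   ranked by $R^2$ (exact ties go to the simpler form). The candidate set is
   age $\{x,\ x^3,\ \sqrt x,\ \log(c-x)\}$, education $\{x,\ 1/x\}$, gender
   $\{x\}$ — the forms that appear in the published equations, plus the
   identity. The shifted-log offset defaults to (observed max age) + 4,
   which reproduces the published $\log(88-\text{Age})$ with max age 84; it
   must exceed the covariate maximum or the candidate is skipped.
2. **Stepwise selection** (`stepwise_fit()`): bidirectional p-value stepwise
   over the (at most three) best-transformed covariates, with entry and
   removal thresholds both 0.05 by default. A p-value criterion was chosen
   over AIC because the selection operates on at most three candidate
   terms, where the conventional partial-t criterion is transparent and the
   two flavours rarely disagree; both thresholds are configurable.
3. **Mean-deviation refit**: the retained covariates and the outcome are
   expressed as deviations from their sample means and refit; the slopes are
   stored **sign-reversed** with their centering constants, so

   $$\text{adjusted} = \text{raw} + \sum_j \beta_j\,\bigl(g_j(x_j) - \bar g_j\bigr).$$

   Centering makes the correction vanish exactly at the sample means (the
   *centering identity*, tested), and adding the sign-reversed fitted effect
   makes the cohort mean of adjusted scores equal the mean of raw scores
   (*mean invariance*, tested).

`build_grid()` tabulates the correction on the clinical lattice (ages 18,
22, 27, …, 82, 84; education rows 5, 8, 13, 16, 18, 21 where education is in
the equation; stratified by gender where gender is), rounding
half-away-from-zero at 2 decimals. All internal arithmetic is unrounded;
rounding conventions exist only at display boundaries. `validate_fixtures()`
recomputes every cell of the shipped published grid from the shipped
published equations; the maximum absolute deviation is below 0.005, i.e. the
grid is reproduced exactly at 2-decimal rounding. Natural log is used in the
shifted-log form — it reproduces the published RAVL-I grid cells, base-10
does not.

## Equivalent Scores and percentiles

Normative interpretation uses non-parametric tolerance limits on the 5th
population centile at 95% confidence, computed from the exact binomial
distribution (`tolerance_limits()`; no normal approximation — the ranks are
reproducible integers and exact computation is cheap at these $n$). The
outer limit (OTL) is the $r$-th order statistic with $r$ the largest integer
such that $F_{\mathrm{Bin}(n,0.05)}(r-1) \le 0.05$; the inner limit (ITL)
uses the smallest $s$ with $F(s-1)\ge 0.95$. At $n = 204$ this gives ranks
5 and 17. The smallest usable sample is $n = 59$
($0.95^{59} \approx 0.0485$); below that the outer rank does not exist and
the function refuses with the minimum stated.

Equivalent Scores are the 5-level ordinal classification standard in Italian
norming: ES 0 at or below the OTL, ES 4 above the sample median, and ES 1–3
partitioning the observations strictly between OTL and median into three
consecutive rank groups of as-equal-as-possible size (remainders assigned to
the lower bands first), each band's upper cutoff being the maximum observed
value in its group. The source literature delegates the intermediate-band
construction to a rank-based procedure without printing formulas; this
equal-frequency-tertile choice is isolated in `es_thresholds()` so an
alternative partition is a one-function change. Band membership uses
inclusive upper bounds (ES $k$ iff $c_{k-1} < x \le c_k$), matching the
"≤ cutoff / > cutoff" convention of published ES tables. Tied cutoffs
collapse with a warning and the thresholds are flagged degenerate.

Percentile tables (`percentile_table()`) use linear interpolation of order
statistics (the type-7 convention), recorded in the output metadata. The
estimator cannot be adjudicated against the published percentile tables
because the raw data are unavailable; those tables are treated as
plausibility fixtures only. The published ES table's VPAL row is numerically
identical to its DSF row — almost certainly a typesetting duplication — and
is flagged `suspect_duplicate` in `published_es_table()`; nothing treats it
as ground truth.

## Comparing two normative systems

`run_comparison()` evaluates how a newly fitted normative system agrees with
a reference system on a patient cohort. Each system is an adjustment
equation plus an impairment rule; the default cutoff is the OTL (ES = 0),
configurable, since the impairment threshold convention is a clinical
choice. The reference system supplies the baseline classification, the new
system the prediction, giving per test:

* **accuracy** $(a+d)/n$;
* **Cohen's kappa** $(p_o - p_e)/(1 - p_e)$ with product-of-marginals
  chance $p_e$, CI from the standard large-sample variance
  $p_o(1-p_o)/\bigl(n(1-p_e)^2\bigr)$;
* **Gwet's AC1** $(p_o - p_\gamma)/(1-p_\gamma)$ with
  $p_\gamma = 2\pi(1-\pi)$, $\pi$ the mean of the two systems' impaired
  proportions — robust to the marginal imbalance that makes kappa
  paradoxical on clinical cohorts; CI from the subject-level linearised
  variance;
* **AUC**: the Mann–Whitney rank statistic of the *continuous* adjusted
  score under the new system against the reference flag, oriented so lower
  scores predict impairment, ties counted half. The continuous score (not
  the binary flag or the ES level) is the predictor because it yields the
  smooth ROC curves a norm comparison reports. The CI uses DeLong's
  placement-value variance by default; a seeded 2000-resample percentile
  bootstrap is available.

All four statistics are authored in this package and tested against
independent oracles: exhaustive pair counting for the AUC, direct formula
evaluation on enumerated 2×2 tables for kappa and AC1, and the pROC
DeLong implementation as a cross-check.

## Synthetic cohorts

`simulate_healthy_cohort()` emulates the published normative sample:
$N = 204$ with 127 females, age 44.33 (18.51) in 18–84, education 14.98
(3.85) in 5–26, the published score means/SDs, and the published 8×8
correlation matrix over (gender, age, education, five scores), with gender
correlations point-biserial. The mechanism is a Gaussian copula: a latent
multivariate normal is drawn, gender is thresholded at the split quantile,
and each continuous variable is quantile-mapped to a truncated normal on its
bounds, then rounded to its granularity (whole years; integer span/recall
points; half points for VPAL). Two calibrations make the generator
faithful rather than merely shaped like the targets:

* the truncated-normal parent parameters are moment-matched so the
  *truncated* marginal hits the target mean exactly and the target SD as
  closely as the family allows on those bounds (asymmetric truncation would
  otherwise bias the age mean upward by more than two years);
* the latent correlation matrix is calibrated by a Hermite-polynomial
  expansion of each output map (the NORTA construction), so the population
  correlations *after* thresholding, quantile mapping and rounding equal the
  targets. Without this, dichotomisation alone attenuates gender
  correlations by a factor of about 0.78. Rounding is applied after the
  copula mapping, which preserves the correlation targets better than
  rounding before.

The calibrated matrix is repaired to positive semidefiniteness by clipping
small negative eigenvalues; a deficit beyond −0.05 is refused with the
offending eigenvalue named, since that indicates inconsistent targets rather
than numerical noise. Over 20 seeds at $n = 204$ the mean absolute deviation
between realised and target correlations is ≤ 0.05, which is the sampling
floor at this sample size.

`simulate_patient_cohort()` emulates the simulated amnestic-MCI comparison
cohort: $n = 100$, each test score drawn Normal(mean, SD), clipped to
catalog bounds and rounded; age and education drawn from a bivariate
Gaussian copula whose latent correlation is iteratively adjusted until the
realised Pearson correlation of the rounded values is within ±0.02 of the
target (−0.22 by default). The per-test clinical means/SDs default to
**synthetic stand-ins** (DSF 5.2 ± 1.1, DSB 3.6 ± 1.2, RAVL-I 28.5 ± 8.0,
RAVL-D 4.0 ± 2.8, VPAL 7.5 ± 3.5; age 72 ± 6.5 in 55–84, education 9 ± 4):
clinically plausible magnitudes for an amnestic-MCI sample, clearly below
the healthy means, chosen once and documented — they stand in for external
clinical norms that are not reprinted here. Patient ages are capped at 84
because the adjustment equations are undefined beyond the age range the
norms cover (the RAVL-I shifted log requires age < 88).

The reference normative systems used by the comparison stage
(`standin_reference_systems()`) are likewise synthetic: simple linear
age/education corrections with cutoffs near plausible older ES-0 limits.
They exercise the machinery; the resulting agreement values characterise the
synthetic configuration, not any historical norms.

What passing tests on these cohorts do **not** show: the generator draws
from smooth unimodal marginals with a single correlation structure, with no
item-level structure, no practice or session effects, no missingness, and no
cohort idiosyncrasies (education–occupation clustering, floor effects in
impaired ranges). Agreement metrics computed on the synthetic patient cohort
are qualitative anchors, not reproductions of published values.

## Sensitivity power analysis

`sensitivity_f2()` solves for the minimal detectable Cohen's $f^2$ of a
fixed-model regression coefficient test: numerator df = number of tested
predictors (default 1, a single-coefficient test), denominator df
$N - p - 1$ with $p = 3$ predictors, noncentrality $\lambda = f^2 N$ (the
G*Power convention, not $f^2(v+1)$), solved by monotone bisection to
$|power - target| < 10^{-10}$. With the df₁ = 1 reading the solver gives
$f^2 = 0.0388$ at $N = 204$ and $0.0441$ at $N = 180$ ($\lambda \approx
7.93$); the df₁ = 3 omnibus reading would give ≈ 0.053 at $N = 204$.
Display rounding is half-away-from-zero at 3 decimals, so the two values
print as 0.039 and 0.044. `power_at()` is the exact inverse; the pair
round-trips to solver tolerance across a grid of $N$ and df₁ (tested), and
a 10,000-replicate Monte-Carlo regression simulation reproduces the target
power within ±0.02.

## Numerical conventions and problem sizes

* Rounding: half-away-from-zero everywhere a value is displayed (grids at
  2 dp, percentiles at 1 dp, $f^2$ at 3 dp); internal arithmetic unrounded.
* JSON serialisation uses 17 significant digits so equations and thresholds
  round-trip bit-exactly.
* All randomness flows from one seed; pipeline stages draw from named
  substreams so each stage is individually reproducible, and `run_pipeline()`
  writes a manifest with MD5 checksums — two runs at the same seed are
  byte-identical.
* Test-suite problem sizes: correlation calibration over 20 seeds at
  $n = 204$; parameter recovery at $n = 2000$ over 20 seeds; tolerance-rank
  oracle equivalence for every $n \in [60, 500]$; exhaustive 2×2 tables to
  $n = 40$ for kappa/AC1 and pair-counted AUC on enumerated tables to
  $n = 12$ plus random larger ones; 10,000 Monte-Carlo replicates for
  tolerance-limit coverage and for power. These sizes keep the whole suite
  within a few minutes on one CPU while leaving each check several standard
  errors of headroom.

## Known limitations

* The intermediate-ES partition and the percentile estimator are documented
  conventions, not reconstructions: the source tables cannot adjudicate
  them without the raw data.
* The stepwise criterion (p-value vs AIC) and the bivariate screening
  criterion ($R^2$) are likewise documented choices where the original
  procedure is underspecified.
* The exact noncentral-F sensitivity solution at $N = 204$ is 0.0388, which
  rounds to 0.039; values this close to a rounding boundary are sensitive to
  display convention, so the unrounded solution is always returned
  alongside the display value.
* Equivalent Scores from $n \approx 200$ place ES 0 on the 5th-or-lower
  centile with wide sampling variability; the ES cutoffs fitted on a
  synthetic cohort differ from the published ones by sampling noise alone.
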