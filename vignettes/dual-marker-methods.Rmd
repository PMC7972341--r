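---
title: "Dual-marker evaluation: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-marker evaluation: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model family

A single predictive biomarker is often too blunt: in immunotherapy cohorts,
for example, tumor mutational burden and an immune-suppressive expression
signature each carry signal, but their combination stratifies patients
better than either alone. `markerpair` formalizes the evaluation of one
marker pair, and the screening of many, around a four-model family fitted
per outcome type:

* logistic regression for a dichotomous response,
* Cox proportional hazards (Efron tie correction) for a time-to-event
  outcome,

with models `outcome ~ M1`, `~ M2`, `~ M1 + M2` and `~ M1 + M2 + M1:M2`,
all on one identical complete-case set so that likelihood-ratio statistics
are valid. The five nested comparisons (each dual model against each single
model, and interaction vs additive) use `2Δℓ ~ χ²` with degrees of freedom
equal to the parameter-count difference; the interaction is also tested by
the Wald z of its coefficient. Covariates, when supplied, enter every model
additively — covariate-by-marker interactions are out of scope, as are
non-linear (e.g. spline) marker effects and ordinal variables with more
than two levels; such variables must be dichotomized beforehand.

Model assumptions are the standard ones of the two regressions: linear
effects on the log-odds / log-hazard scale, proportional hazards,
independent censoring. The package deliberately reports nominal p-values as
an exploratory prioritization device, not confirmatory inference.

## Dichotomization and quadrants

Continuous markers enter the models **raw and unscaled**; dichotomization
(population median by default, or a user cutoff) exists only for
stratified visualization and quadrant statistics. A sample is "high" iff
its value is **strictly greater** than the cutpoint. The tie direction at
the median is a genuine convention choice; strict `>` makes the sample at
the median itself "low", which keeps behavior deterministic under heavy
ties, and a `strict_gt = FALSE` flag flips the rule for users who prefer
`≥`. A marker whose median cut leaves a single level (extreme tie mass) is
rejected rather than silently producing an empty stratum.

Quadrants follow the fixed mapping R1 = M1-high/M2-high, R2 = low/high,
R3 = low/low, R4 = high/low, with one fixed color per quadrant across every
figure of a report. Missing data are handled by complete-case (pairwise)
deletion per analysis — never imputation, which would add unstated
modeling to an exploratory tool.

## Statistics conventions

* **Response rates**: Clopper–Pearson exact intervals (beta quantiles);
  Wilson is available as an option. The exact interval matches the
  conservative convention of exact binomial testing used elsewhere in the
  report.
* **Wilcoxon rank-sum**: exact enumeration when both groups have ≤ 25
  observations and no ties; otherwise normal approximation with tie and
  continuity correction.
* **Spearman**: average-rank rho with the t-approximation p-value at every
  n, for determinism (no permutation path).
* **Fisher's exact test**: two-sided by summing hypergeometric
  probabilities ≤ that of the observed table; the reported effect is the
  *sample* odds ratio (Haldane–Anscombe +0.5 only when a cell is zero),
  not the conditional MLE — the OR is descriptive here.
* **Kaplan–Meier**: Greenwood variance, pointwise intervals on the
  log-survival scale; the median is the smallest time with survival ≤ 0.5
  and its CI comes from intersecting the pointwise bounds with 0.5, either
  side possibly undefined.
* **Conditional KM**: four stratified two-group log-rank tests (M2 within
  each M1 level, M1 within each M2 level), Bonferroni-adjusted with family
  size fixed at 4 — all four comparisons are treated as one family, so a
  non-evaluable stratum does not shrink the multiplier.
* **AUC**: Mann–Whitney statistic with DeLong variance. ROC curves —
  including single-marker ones — are computed on fitted probabilities of
  the corresponding logistic model, so a marker negatively associated with
  response still plots with AUC ≥ 0.5 and all four curves are comparable
  on one panel. (On training data this makes model 4's AUC ≥ model 1's by
  construction; the AUCs are descriptive, not cross-validated.)
* **CPE**: the asymptotic Gönen–Heller concordance probability computed
  from linear predictors only, `mean 1/(1 + exp(−|η_i − η_j|))` over
  unordered pairs; the smoothed variant and its variance are not
  implemented (only point values are reported).

## The search rule

For a candidate partner, both dual models are compared with a single-marker
model and **the smaller LRT p-value is taken** (the additive comparison has
df 1, the interaction comparison df 2; ties go to the additive model). The
min-of-two rule is taken literally rather than, say, pre-selecting a dual
model by AIC. It mildly inflates the null rejection rate (the package's own
simulations place it near 0.05–0.12 at nominal 0.05), which is accepted and
documented: the score is an exploratory ranking device, and
Benjamini–Hochberg adjustment is applied column-wise — separately to the
dual-vs-M1 and dual-vs-M2 columns, across evaluated candidates only.

The signed score is `−log10 p` with a positive sign when the candidate's
*single-marker* effect is favorable: higher response odds for the logistic
family, longer survival — i.e. a negative log-hazard coefficient — for the
Cox family. `p = 0` underflow is capped at 300. Degenerate candidates are
skipped with a recorded reason rather than erroring a whole screen:
constant markers, |r| > 0.999 collinearity with M1, quasi-separation
(|coefficient| > 15 or non-convergence), monotone partial likelihood, or
fewer than the minimum complete cases (20), per-class counts (5) or events
(10). All thresholds are arguments.

## Numerical choices

Logistic fits use IRLS and Cox fits Newton iterations, both to a relative
log-likelihood change below 1e-9 with at most 25 iterations. LRT statistics
are clipped at zero (they can be epsilon-negative numerically); comparisons
across different complete-case sets are a hard error, preventing silent
missing-data bias. Rank-deficient columns are reported as zero effect with
infinite standard error. Efron is the only tie method used for reported
results; Breslow exists for cross-checking because the two must diverge on
tied data and agree without ties.

## What the synthetic generator does and does not emulate

`simulate_cohort()` draws markers from declared distributions (normal,
lognormal, Bernoulli), response from the logistic model with intercept,
two marker effects and an interaction, and event times from an exponential
proportional-hazards model with exponential and/or administrative
censoring. The exponential baseline was chosen over Weibull because it
gives closed-form oracles (event fraction `λ/(λ+λc)`, marginal rates) for
testing. Defaults emulate a mid-size checkpoint-inhibitor trial: n = 200,
~30% responders (`b0 = −0.85`), median baseline survival of 12 time units,
censoring at 3/7 of the baseline hazard (≈30% censored under the null).
Decoy candidates are mutually independent standard normals.

Real cohorts differ in ways the generator does not model: correlated
co-expressed markers, non-proportional hazards, informative censoring,
heavy-tailed marker distributions, batch structure. Passing calibration
and recovery checks on these simulations therefore demonstrates that the
machinery is correct under its stated model, not that any particular
biological pair will validate.

## Scale of the package's own checks

The test-suite calibration and power studies use sizes chosen to make the
Monte-Carlo error small relative to the asserted bands: 1000 replicates at
n = 200 for type-I error of the dual-vs-single LRT (both families, asserted
within [0.035, 0.065] at α = 0.05); 200 replicates at n = 2000 for 3-SE
coefficient recovery of the interaction model (≥ 95% coverage per
coefficient); 100 replicates for search ranking (one true additive partner,
effect 1 SD-unit, n = 400, among 50 decoys) and for interaction detection
(log-HR 2.5 interaction at n = 500). Oracle equivalences (AUC vs explicit
pair counting, CPE vs an O(n²) loop, exact tests vs full enumeration) are
asserted to 1e-12 or exactly.

## Known limitations

Training-set AUC/CPE favor larger models; no cross-validation is offered.
The min-p search rule is anti-conservative by design (see above). Only
pairs — no triplets or higher — are considered, and very large panels run
serially (`comb_m` is quadratic in the panel size). Figures are static
exports; palettes are a simple named-vector hook.
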