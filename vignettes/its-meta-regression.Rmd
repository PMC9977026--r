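---
title: "Interrupted time series meta-regression for aggregated school scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interrupted time series meta-regression for aggregated school scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

## The problem

After a community-wide event — a mine fire, a flood, a prolonged school
closure — one often wants to know whether academic progress in the affected
area was set back, and by how much. Individual student records are usually
restricted, but aggregated school-level results (the mean score of each
school × grade × year cell, together with the standard error of that mean)
are far easier to obtain. itsmeta implements an analysis built entirely on
such aggregates: a Bayesian interrupted time series hierarchical
meta-regression, plus a synthetic-data generator that reproduces the
statistical structure of a realistic school panel so that every stage of the
pipeline can be exercised and validated with known ground truth.

## The model

Each observation is one cell: school $s$, grade $g$, student cohort $c$, one
testing domain, one calendar year. Scores are first *centred*: the regional
average score for the same year, grade and domain is subtracted, which
removes the grade ladder (about 420 points at grade 3 rising to about 580 at
grade 9) and any region-wide secular drift. Scores are deliberately not
standardized — a centred score difference stays in score points, which is
what makes conversions like "points per year of learning" meaningful.

The centred cell mean $y_{s,g,c}$ with known sampling standard error
$\tau_{s,g,c}$ is modelled as

$$
y_{s,g,c} \sim N\!\left(\mathbf{X}_{s,g}\beta + \theta_{s,c} + \theta_s +
\theta_e,\; \tau_{s,g,c}^2\right),
$$

with nested random intercepts $\theta_s \sim N(0, \sigma_s^2)$ for schools,
$\theta_{s,c} \sim N(0, \sigma_{s,c}^2)$ for cohorts within schools, and a
cell-level residual $\theta_e \sim N(0, \sigma_e^2)$. Because every term is
Gaussian, the cell residual can be folded into the observation variance
exactly — the likelihood the sampler actually uses is
$y_i \sim N(X_i\beta + \theta_{s(i)} + \theta_{c(i)}, \tau_i^2 + \sigma_e^2)$
— which removes one latent vector per cell at no cost in fidelity.

Weighting by the known sampling variances is what makes this a
*meta-regression*: a school with 100 tested students carries more
information than one with a dozen, and an unweighted regression of cell
means would both waste power and bias results toward small schools.

A *cohort* is the set of students progressing together through the biennial
test grades: grade 3 in 2014 and grade 5 in 2016 at the same school are the
same children. Cohorts are labelled by the year the cohort sat (or would
have sat) grade 3, `cohort_id = year - (grade - 3)`, which reproduces that
pairing at every grade. Grade 9 cohorts never reappear; their random effect
still groups the single appearance.

### Interrupted time-series terms

The fixed-effects design contains seven segmented-regression columns:

| column | meaning |
|---|---|
| `T` | years since the first study year (0, 1, 2, ...) |
| `E_m`, `E_h` | moderate / high exposure-group indicators (no/low is the reference) |
| `E_m:I_post`, `E_h:I_post` | interruption (level shift) from the event year onwards |
| `E_m:I_post:T_post`, `E_h:I_post:T_post` | post-event change in annual slope; `T_post` is 0 through the event year, then 1, 2, ... |

`E_m:I_post` and `E_h:I_post` are the quantities of interest: the immediate
level shift of each exposed group relative to its own pre-event trajectory
and to the unexposed control group. The post-trend terms measure recovery
(positive) or continued decline (negative). The control group is assumed to
carry no interruption of its own; it identifies the common trend `T`.

Confounders enter alongside: ICSEA (a school socio-educational advantage
index), total enrolments, proportion of girls, a non-government sector
indicator, and grade-level indicators with grade 3 as reference. Grade
enters categorically, not linearly, because centring has already removed
the grade-level mean structure and no functional form is assumed for what
remains. Continuous covariates are centred at the sample mean and scaled by
the sample SD for sampler conditioning; reported coefficients are
back-transformed to natural units, and the design records the scaling so
the transformation is exact. One model is fitted per testing domain;
exposure effects are pooled across grades (no grade × exposure
interactions), and no random slopes, nonlinear trends, or autocorrelation
structures are modelled.

### Priors

All fixed effects get $N(0, 50^2)$ — weakly informative on the centred-score
scale, where effects beyond ±100 points are not credible. The three SDs get
truncated-normal priors $TN(10, 5^2)$ with support $(0, \infty)$: between-
and within-school spreads of the order of 10 centred points are plausible a
priori, and zero is the natural truncation bound for a standard deviation.
Any SD prior can be replaced by a fixed value; fixing it at 0 removes the
component, which is how the package expresses the oracle limits used in its
tests and the "no cohort random effect" sensitivity variant.

## Sampling

The posterior is simulated by a blocked Gibbs sampler written for exactly
this model:

1. $(\beta, \theta_s)$ drawn jointly from their Gaussian full conditional
   via one Cholesky factorization of the $(p + S)$ precision matrix.
   Sampling the school effects jointly with the fixed effects eliminates
   the strong posterior correlation between school-level (and nearly
   school-level) covariate coefficients and the school intercepts that
   makes one-at-a-time updates mix slowly.
2. $\sigma_s$ updated by univariate slice sampling with the school effects
   *integrated out* (each school contributes a rank-one covariance term,
   handled by the matrix determinant lemma), then $\theta_s$ redrawn given
   the new value. Collapsing removes the classic funnel between a variance
   and its effects.
3. $(\sigma_{s,c}, \sigma_e)$ updated the same collapsed way with the
   cohort effects integrated out, then $\theta_{s,c}$ redrawn; an
   interweaving (translation) move between the intercept-like columns and
   the cohort effects follows.

Conditional on the SDs every draw is exact, so there are no step-size
parameters, no divergent transitions, and the only Monte-Carlo tuning is
chain length. The centred parameterization with collapsed SD updates was
chosen over a non-centred one because non-centring is a remedy for
gradient-based samplers; under conjugate blocked Gibbs the collapsed
centred scheme gives effective sample sizes of several hundred per
thousand iterations for every parameter on the default study.

Defaults are 4 chains of 2000 iterations with the first half discarded as
warmup. Convergence is summarized by split-$\hat R$ over all chains and by
effective sample sizes; $\hat R > 1.01$ triggers a warning — chains are
never silently repaired or discarded. Short exploratory chains (a few
hundred kept draws) can trip this threshold by chance; the warning is
advice to look, not an error.

Each coefficient is reported as its posterior mean, 2.5/97.5 percentile
credible interval, and the tail probabilities $P(\beta < 0)$ and
$P(\beta > 0)$ computed as draw fractions. Predicted margins fix all
confounders at reference values (sample means for continuous columns, modal
category for indicators), set the random effects to zero, and trace the
fitted centred score per year and exposure group — the package's analogue
of a predicted-trends figure. A score-point effect divided by 27 points per
school year and multiplied by 12 converts to months of learning.

## The synthetic-data generator

`generate_study()` emulates the structure of the motivating study
population and is the package's test bed. Its defaults are fixed study
conditions, not tuning knobs:

* 69 schools split 34/28/7 across no/low, moderate and high exposure;
  years 2008–2018 with the event in 2014; grades 3/5/7/9; five domains.
* ICSEA drawn per school around group means 974/962/922 (SD 40), matching
  the lower socio-educational profile of the high-exposure area;
  enrolments log-normal per group (medians 108/165/204); proportion of
  girls Beta-distributed around 0.49; sector and school type drawn with
  the observed group proportions (87% primary, 12% secondary, one
  combined school in the population).
* Primary schools teach grades 3 and 5, secondary 7 and 9, combined all
  four. Cell sizes are drawn log-normally around enrolments divided by the
  school's grade span (7 levels for primary, 6 secondary, 13 combined),
  floored at 5 students; the standard error of a cell mean is exactly
  `within_school_sd / sqrt(n)` with a default within-cell student SD of
  70 points, a plausible magnitude for individual standardized test
  scores. Neither cell sizes nor within-school SDs are reported for the
  motivating population, so these two defaults are plausible stand-ins
  chosen once, not calibrated values.
* Ground-truth effects default to an interruption of −10 points and a
  post-event recovery slope of +2 points/year in the high-exposure group,
  −2 and +0.5 in the moderate group, a −1 point/year background trend,
  and SDs of 5 for school, cohort and residual components. Confounder
  effects apply to covariate deviations from regional-typical values
  (ICSEA 960, 150 enrolments, 49% girls), so a typical unexposed school
  tracks its reference mean.
* An optional missingness rate thins school × year × grade cells to
  emulate the incomplete panels of real administrative data (default 0).

What the generator deliberately does *not* emulate: spatial structure of
exposure (the group label is taken as given), individual students,
participation-rate fluctuations, score floors/ceilings, or serially
correlated shocks. Passing recovery tests on these synthetic panels
therefore demonstrates that the estimation machinery is correct under the
model's own assumptions — it cannot certify those assumptions against any
particular real dataset.

### What the tests show

The test suite checks the chain of logic at increasing depth: exact
arithmetic for codings, cohort assignment and centring; closed-form
conjugate posteriors for the intercept-only limit; agreement with
inverse-variance weighted least squares when the variance components are
pinned at zero; agreement with two independent implementations (REML
meta-regression via metafor, and the same hierarchical model in JAGS) on
small studies; and parameter recovery with nominal-level credible-interval
coverage over 20 replicated synthetic studies (run at 2 chains × 1000
iterations per replicate to keep the suite fast).

One caveat worth stating: with only 7 high-exposure schools, the sampling
distribution of the high-group interruption estimate is noticeably
heavier-tailed than its model-based standard error suggests (replicate
experiments put the spread some 20% above the average reported SE, with
credible-interval coverage near 90% rather than 95%). This is the familiar
few-groups small-sample effect of variance-component models, inherited
from the study design rather than the implementation; single-study
estimates of that contrast should be read with it in mind.

## Numerical choices and degenerate inputs

* Cells with non-positive or missing SEs are reported and dropped, never
  imputed — the SE is the meta-analytic weight, and imputing it would
  silently distort the weighting.
* The regional reference mean is treated as a known constant when
  centring (no SE propagation): the reference pool is far larger than any
  single cell. This is a documented approximation.
* Profile gaps are filled by carrying the last observed profile year
  forward, with a message; observations with no profile at or before
  their year are an error.
* Structurally empty design columns (for instance the exposure block when
  only control schools are present) are dropped by name; remaining rank
  deficiency is an error that names the collinear columns.
* Fixing an SD at zero removes the component exactly rather than
  sampling near zero, so oracle limits are exact.
* The master pipeline seed deterministically derives per-stage seeds
  (`seed + 1009 × stage`), making full and partial reruns byte-identical.

## Sensitivity analyses

`run_variant()` re-fits with one declared modification: alternative SD
priors, removing the cohort random effect (school clustering only), or
excluding named schools (for instance schools relocated during the event),
with the design rebuilt after exclusion so covariate scaling reflects the
reduced sample. Variants reuse the base seed so differences reflect the
modification rather than Monte-Carlo noise, and `compare_variants()` lays
the resulting tables side by side with sign-agreement flags on the
segmented-regression terms. Excluding every school of an exposure group is
refused: the group's coefficients would be unidentifiable.

## Problem sizes

The default single-domain study produces roughly 1,500 cells, 69 school
effects and about 900 school-cohort effects; one 4 × 2000 fit takes tens of
seconds on a single core, and the 20-replicate recovery study runs at
2 chains × 1000 iterations per replicate. These sizes were chosen to make a
full validation cycle comfortable on a laptop while matching the
motivating study's dimensions exactly where they are known (schools,
years, grades, domains, group sizes).
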