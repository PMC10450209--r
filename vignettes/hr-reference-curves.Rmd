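---
title: "Reference centile curves and prediction equations for adolescent heart rate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference centile curves and prediction equations for adolescent heart rate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrcentiles)
```

## The problem

Maximum heart rate (MHR) anchors training-intensity prescriptions: a
percentage of MHR corresponds, through the near-linear relationship
between heart rate and oxygen uptake, to a fraction of maximal aerobic
effort. When MHR cannot be measured directly it is predicted from age,
classically with the Fox (`220 - age`) or Tanaka (`208 - 0.7 * age`)
equations, both calibrated on adults. For adolescent athletes two
complementary tools are more informative: age-conditional *reference
centile curves* of MHR and resting heart rate (RHR), which place an
individual within their age group's distribution, and a
population-specific *prediction equation*. This package implements both,
together with the agreement analysis used to compare prediction
equations, and a fully seeded synthetic-cohort generator so that every
stage can be exercised end to end without any external data.

## The LMS model

A positive measurement `x` at age `t` is modelled by the Box-Cox
Cole-Green (BCCG) family: three age-varying parameters — the Box-Cox
power `L(t)` (skewness), the median `M(t)` and the coefficient of
variation `S(t)` — map `x` to a standard-normal deviate

$$ z = \frac{(x/M)^L - 1}{L\,S} \;\; (L \neq 0), \qquad
   z = \frac{\log(x/M)}{S} \;\; (L = 0), $$

so the centile of order $100\alpha$ is
$C_{100\alpha} = M (1 + L S z_\alpha)^{1/L}$ with $z_\alpha$ the normal
quantile. `bccg_centile()`, `bccg_zscore()` and `rbccg()` implement the
forward, inverse and sampling forms; they switch to the exact log-normal
limit when $|L| < 10^{-7}$ so the family is numerically continuous.

### Fitting strategy

`lms_fit()` uses a deliberately two-stage scheme:

1. each integer age group is fitted by maximum likelihood
   (`fit_bccg()`), maximising
   $\ell = \sum_i [\,L \log(x_i/M) - \log S - z_i^2/2\,]$ on the
   unconstrained scale $(L, \log M, \log S)$ from the Gaussian start
   $(1, \log \tilde{x}, \log(\mathrm{sd}/\tilde{x}))$, Nelder-Mead
   followed by a BFGS polish, converged at successive log-likelihood
   changes below $10^{-10}$;
2. the per-age $L$, $M$, $S$ sequences are smoothed across age by cubic
   smoothing splines with fixed equivalent degrees of freedom
   (defaults `L = 3`, `M = 5`, `S = 3`; `M` and `S` on the log scale to
   preserve positivity).

Joint penalised-likelihood estimation of all three curves at once (with
automatic roughness selection) is intentionally out of scope: the
two-stage scheme gives each stage an independent oracle — the per-age ML
step is checked against a brute-force likelihood grid, the smoother
against its fixed points — at the cost of slightly less efficient use of
information across neighbouring ages. With eight age groups of roughly a
hundred athletes each, that cost is small; the default degrees of
freedom allow mild curvature in the median and keep the skewness and
spread curves close to linear, which is the behaviour reference charts
of this kind display. Smoothing is skipped entirely below four age
groups, where a spline is not meaningful.

Two numerical conventions matter in the tails: a centile request for
which $1 + L S z_\alpha \le 0$ is an error naming the infeasible tail
(not an extrapolation), and random BCCG draws falling outside the
support of the power transform are rejected and redrawn (for the
parameter ranges here this occurs with probability far below $10^{-6}$).

## What the synthetic cohorts emulate

`cohort_config()` defaults define the study conditions the package
models: 801 male players in integer age groups 11-18 with group
proportions 12.23, 10.61, 13.61, 13.48, 13.11, 12.86, 10.99 and 13.11
percent; MHR drawn from `225.08 - 1.55 * age` with Gaussian residual SD
5.22 bpm; RHR declining linearly between the median anchors 73.86 bpm at
11 and 63.64 bpm at 18. Every one of those defaults is a published
quantity; parameters nothing was published for were fixed once at
field-realistic values and are not tuned:

* the RHR residual SD defaults to 5.8 bpm, the spread implied by the
  published P3-P97 band at age 11 under a Gaussian approximation;
* anthropometrics are age-linear in the mean (height 1.45 m to 1.76 m,
  body mass 38 kg to 68 kg, Gaussian; single-site skinfolds log-normal
  with medians declining from 9 mm to 7 mm), typical of male adolescent
  soccer players; they feed only BMI/body-fat computation and the
  stepwise candidate pool;
* `trainability` is carried as an opaque auxiliary covariate (a noisy
  age-increasing score) so the stepwise candidate pool has the same
  shape as a descriptive cohort table; it has no effect on MHR in the
  generator.

An optional BCCG mode (`bccg_anchors`) replaces the linear-plus-noise
draw for a measure by per-age BCCG sampling with `L`, `M`, `S` linearly
interpolated between anchor ages — the configuration used to exercise
the LMS machinery on data that genuinely follow the BCCG law (anchored
at the published endpoint medians with `L = 1`, `S = 0.03` for MHR, the
coefficient of variation implied by the published P3-P97 band).

Randomness follows one master seed; each stage (ages, heights, masses,
each skinfold site, RHR, MHR, trainability) derives its own substream
from a stable text label, so adding or removing a stage never perturbs
another stage's draws and identical configurations are bit-identical.

What the generator does *not* emulate: within-year fractional ages
(ages are integer groups, as in the reference tables), correlation
between height and mass (BMI is therefore somewhat more dispersed than
in a real cohort), secular or seasonal effects, and measurement error in
HR monitors. Passing tests therefore demonstrate that the estimators
recover the structure they assume, not that real adolescent data follow
that structure.

## Prediction equations and agreement

`fit_ols()` reports the conventions of this literature: the standard
error of the estimate $\mathrm{SEE} = \sqrt{SSE/(n - p - 1)}$, $R^2$,
and the in-sample residual range. `stepwise_select()` is classic
forward-entry / backward-removal on partial-F p-values with the
textbook thresholds `p_enter = 0.05`, `p_remove = 0.10` (none were
published; these are the SPSS defaults a study of this kind would have
used). The returned model *sequence* — the fit after each successful
entry — mirrors how "Model 1, Model 2" tables are constructed.

`bland_altman()` fixes the difference sign convention as
`measured - predicted` throughout: an equation that predicts too high
shows a negative bias. Under the default generator this makes the Fox
bias negative and the Tanaka bias positive, and those directions are
asserted in the test suite. Limits of agreement use
$\mathrm{bias} \pm 1.96 \times \mathrm{SD}$ with the sample
($n-1$) SD — the convention that reproduces published limits from
published (bias, SD) pairs exactly. `group_compare()` runs one-way
ANOVA plus pooled-variance t-tests for *successive* age pairs only,
Bonferroni-corrected by the number of successive comparisons (seven for
eight age groups), matching the comparison structure of descriptive
tables; the correction is multiplication capped at 1.

The Durnin-Womersley body-density equation and the Siri conversion are
implemented exactly as printed; the Siri expression `4.95/D - 4.50`
yields a fraction, and `body_fat_percent()` reports it multiplied by
100, matching the "BF %" convention (otherwise "percent" values would
sit near 0.1).

## Worked example

```{r pipeline}
bundle <- run_pipeline(cohort_config(seed = 1), quiet = TRUE)
bundle$percentile_tables$mhr_bpm[, c("age", "P3", "P50", "P97")]
bundle$models$model1_refit
bundle$agreement$fox
decline_summary(bundle$percentile_tables$mhr_bpm$P50, units = "bpm")
```

```{r fan-chart, fig.width = 6, fig.height = 4}
plot(bundle$curves$mhr_bpm)
```

## Problem sizes, tolerances, and degenerate inputs

The test suite and the acceptance script run everything at the sizes
the analysis is designed for: cohorts of 801 (or 100 per age for the
BCCG-anchored runs), with 10-20 replicate seeds where a quantity is
stochastic, and $10^4$-$10^5$ draws where a distributional property is
checked against its closed form. Tolerances are derived from asymptotic
standard errors (typically three SEs of the quantity or of its
seed-average), never from the observed outcome. One caveat worth
stating: with a coefficient of variation near 0.03 the skewness
information in a sample is small, so the per-sample ML estimate of `L`
has an asymptotic SE around 0.24 even at $n = 10^4$; `L`-recovery is
therefore asserted on seed-averages, while `M` and `S` recover tightly
per sample.

Degenerate inputs fail loudly rather than silently: constant groups,
undersized groups (fewer than 20 per age by default), singular designs,
zero-variance responses, singleton comparison groups, infeasible tails
and out-of-range ages are all errors with the offending age, row or
column named. Reported tables are never rounded internally; rounding to
two decimals happens only at the presentation layer, and every file the
report writer emits carries 17 significant digits so a rounded value
always has an unrounded counterpart.

## Known limitations

* The two-stage LMS fit is slightly less efficient than joint penalised
  likelihood; with fewer than ~50 athletes per age group the smoothed
  `L` curve in particular is noisy.
* Reference curves are cross-sectional and male-only by construction of
  the default configuration; no longitudinal or sex-stratified modelling
  is attempted.
* The generator's independence assumptions (height vs mass, RHR vs MHR
  within athlete) make some derived quantities — BMI spread, pooled
  correlations — more dispersed than field data.
* Stepwise selection inherits the known optimism of partial-F entry;
  the package reports the selection trace so the path is auditable.
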