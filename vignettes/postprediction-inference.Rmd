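---
title: "Correcting inference on machine-learning-predicted outcomes"
author: "predinfer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correcting inference on machine-learning-predicted outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(predinfer)
```

## The inference problem

A regression whose dependent variable is a machine-learning prediction
rather than an observed outcome no longer estimates what it appears to
estimate. The prediction `yp = f̂(x)` targets the conditional mean of `y`,
so the naive fit of `yp` on covariates has roughly the right coefficients
when the predictor is good, but its residual variance reflects only the
part of `Var(y|X)` the predictor failed to smooth away. Standard errors
shrink, t statistics inflate, and false positives accumulate — regardless of
which machine-learning model produced the predictions.

`predinfer` corrects this by modelling not the machine-learning model but
the *relationship between observed and predicted outcomes*, estimated on a
testing set where both are available. The package assumes the standard
three-way split with one shared data-generating distribution:

1. **train**: fit any predictor (`train_predictor()`; GAM, k-NN, random
   forest, or a user-supplied `custom` fit/predict pair);
2. **test**: fit the relationship model (`fit_continuous_relationship()`,
   `fit_categorical_relationship()`);
3. **validation**: fit the inference model and correct it
   (`correct_analytical()`, `bootstrap_draws()` with
   `summarize_parametric()` / `summarize_nonparametric()`).

The relationship model is deliberately simple. For continuous outcomes it is
the linear regression `y = γ₀ + γ₁·yp + ε`, `ε ~ N(0, σᵣ²)`, with `σ̂ᵣ` the
usual residual SD on `n − 2` degrees of freedom. For binary outcomes it is a
logistic regression of the observed label on the predicted *probability* of
the positive class — the hard label would leave no room to model outcome
variability. Empirically this simple model describes the observed-predicted
relationship well across very different learners; that fitness is the
method's central assumption, and it fails for weak learners whose
predictions correlate poorly with the outcome (see *Limitations*).

## The analytical correction

For a linear inference model `y(val) | X ~ N(Xβ, σ²)` the correction has a
closed form. Writing `β̂ₚ` and `σ̂ₚ` for the coefficients and residual SD of
the naive OLS fit of `yp` on the validation design `X` (intercept always
included), the corrected quantities are

* estimate: `β̂* = (XᵀX)⁻¹ Xᵀ (γ̂₀ + γ̂₁ X β̂ₚ)` — implemented literally as
  this projection, which with an intercept column reduces to
  `γ̂₁ β̂ₚⱼ` for slopes and `γ̂₀ + γ̂₁ β̂ₚ₀` for the intercept, with no
  special-casing;
* standard error: `SE(β̂*ⱼ) = sqrt([(XᵀX)⁻¹]ⱼⱼ (σ̂ᵣ² + γ̂₁² σ̂ₚ²))` — the
  law-of-total-variance decomposition of `Var(y|X)` into the relationship
  residual variance plus the slope-scaled variance of the naive fit;
* statistic: their ratio, referred to a standard normal (two-sided).

Two sanity reductions anchor the implementation and are asserted in the test
suite: if predictions were perfect (`γ̂₀ = 0, γ̂₁ = 1, σ̂ᵣ = 0`) the
correction is the identity on the naive fit; if the predictor is a stub that
returns the observed outcome itself, the whole pipeline collapses to
classical OLS inference on `y` to 1e-10.

The reference distribution is a deliberate choice: no finite-sample df
correction mixing the testing-set and validation-set sizes is available, so
the normal is used and documented. The rmse-based operating characteristics
below are insensitive to this choice.

## The bootstrap corrections

For general GLM families the correction is a bootstrap that re-injects the
prediction error. Per iteration `b = 1..B`: resample validation rows
(predictions and covariates jointly) with replacement; draw outcomes from
the relationship model at the resampled predictions — normal draws for
continuous relationships, Bernoulli draws at
`plogis(γ̂₀ + γ̂₁·pr)` for binary ones (multinomial sampling per row covers
3+ classes); refit the inference model; record `β̂ᵇ` and `SE(β̂ᵇ)`. The
corrected estimate is `median(β̂¹..β̂ᴮ)`; the corrected SE is
`median(SE(β̂¹)..SE(β̂ᴮ))` (parametric flavor) or `SD(β̂¹..β̂ᴮ)` with the
`B − 1` denominator (nonparametric flavor). Even draw counts use R's
standard mid-mean median convention.

Numerical conventions worth knowing:

* One RNG stream is consumed in the fixed order (row resample, outcome draw)
  per iteration, so a run is reproducible bit-for-bit from `(seed, B)`; the
  test suite holds the implementation to a literal step-by-step
  transcription of the procedure sharing the same stream.
* Bootstrap GLM fits that fail to converge or separate (|coef| > 30, or
  non-finite SE) are dropped and counted, never retried — retrying would
  bias the draw distribution. More than 20% dropped draws is an error.
* `B = 100` by default, the value used by the binary reference study; the
  continuous study keeps the same default.
* Logistic fits run through `stats::glm.fit` with `maxit = 100` and
  `epsilon = 1e-10` (deviance-change criterion).

## The simulation scenarios

The simulators are the package's test surface, and their defaults are the
reference study conditions, not knobs.

**Continuous scenario** (`generate_continuous()`): `x1, x2, x3 ~ N(1,1)`,
`x4 ~ N(2,1)`, `eu ~ N(0,1)`,

```
y = β₁·x1 + 0.5·x2 + 3·smooth(x3) + 4·smooth(x4) + eu
```

with 900 rows split 300/300/300, a GAM (one spline per covariate, smoothness
by GCV, via `mgcv`) as the predictor, `β₁` swept over −6..6, 300
replicates. `smooth()` is Tukey's 3RS3R compound running-median smoother
(`tukey_smooth_3rs3r()`, delegating to `stats::smooth`).

Two properties of the smoother shaped design decisions here:

* *Row order matters.* Running medians couple each row to its neighbours in
  the sequence the column was generated in. Smoothing the column in sorted
  order would be a no-op — running medians leave monotone sequences
  unchanged — and would silently delete the smoothed terms from the model.
  The generator therefore smooths the column in its generated row order;
  the smoothed terms are then only partially recoverable from the
  covariates, which is precisely what makes the prediction problem hard
  enough to need correcting.
* *One compound pass is not idempotent.* The splitting step runs once
  between the two rounds of repeated medians, and the second round can
  create a new extremal two-flat. The tests assert the property that does
  hold: repeated passes reach an invariant fixed point within a few
  iterations. An independent reference implementation of the compound
  smoother (medians, end rules, split rules and the pass's keep/discard
  bookkeeping) lives in the test helpers and must agree with the package
  bit-for-bit on random Gaussian series.

**Binary scenario** (`generate_binary()`): `x1 ~ N(1,1)`, `x2 ~ N(2,1)`,
`xc` uniform over {A, B, C}, `eu ~ N(0,1)`,

```
z  = 1·1(xc=B) + βC·1(xc=C) + 1·smooth(x1) − 2·smooth(x2) + eu
y  ~ Bernoulli(1 / (1 + e^{−z}))
```

with 1,500 rows split 500/500/500, a k-NN classifier (k = 5, continuous
features standardized by training mean/SD, categorical features one-hot
encoded) as the predictor, `βC` swept over −2..5 in steps of 0.5, `B = 100`,
300 replicates. The inference model is the logistic regression of the
outcome on the single indicator `1(xc = C)`.

At extreme `βC` the outcome-by-indicator table becomes sparse and every
method's logistic fit destabilises. `flag_sparse_replicate()` excludes a
replicate when any outcome-by-level cell of the validation set — for the
observed outcome *or* the predicted labels — falls below 2. Checking
predicted labels too is this package's reading of "unstable for all
approaches": the naive fit runs on predicted labels and separates exactly
when one of *its* cells empties. The threshold is an exposed argument.

**Correlation sweep** (the `correlation_sweep` scenario): the continuous
generator with N(0, sd) noise added to *training* outcomes only, degrading
the predictor without touching the test or validation sets. It is the vehicle for type-I-error studies
across prediction qualities.

## What the harness measures

`run_experiment()` runs a scenario end-to-end per replicate and records, for
the coefficient of interest, the estimate, SE and t statistic of five fits:
the observed-outcome gold standard, the uncorrected predicted-outcome fit,
the analytical correction (linear models only), and both bootstrap
corrections. `summarize_experiment()` pools the rmse of each method against
the gold standard over all included replicates — the quantity the acceptance
suite asserts. All randomness flows from the single scenario seed, so the
record table is exactly reproducible.

The acceptance tests (`tests/testthat/test-acceptance.R`) and
`scripts/acceptance.R` run both scenarios at the full 300 replicates; a run
takes roughly a minute of CPU. Reference magnitudes asserted there: in the
continuous study the uncorrected SE rmse sits near 0.09 versus roughly
0.01–0.02 for all corrections, and the uncorrected t-statistic rmse near 26
versus below 3 corrected — a five-to-tenfold separation. In the binary study
the uncorrected estimate rmse is several times the corrected one, with the
corrected t statistics showing the expected slight conservative shift.

Type-I error is checked on the correlation sweep at moderate prediction
quality (cor(y, yp) ≈ 0.45): over 500 null replicates all three corrections
reject within the 95% binomial band around 5% while uncorrected inference
rejects at several times the nominal level.

## Limitations

* The corrections inherit the relationship model's fitness. With very
  accurate predictors they run mildly conservative at the null — the
  corrected variance `σ̂ᵣ² + γ̂₁²σ̂ₚ²` slightly overstates `Var(y|X)`
  because conditioning on `yp` discards covariate information. With weak
  predictors (correlations below roughly 0.4 in the sweep scenario) the
  simple relationship model no longer captures the observed-predicted link
  and the corrections become anticonservative; no correction here
  substitutes for a usable predictor.
* Inference covariates must be a subset of the prediction features;
  introducing new covariates downstream violates the relationship model's
  transportability and is unsupported.
* The continuous relationship model is homoskedastic and linear; the
  categorical one is logistic-in-probability (or k-NN-in-probability for
  3+ classes). No heteroskedastic or nonlinear variants are provided.
* The simulators emulate fully specified generative models with i.i.d.
  rows and identical distributions across the three splits. Passing tests
  say nothing about batch effects, covariate shift between splits, or
  dependent sampling in real data — the same-distribution assumption is the
  method's, and violations require upstream normalisation before these
  corrections apply.
* k-NN settings materially affect the binary study: k = 5 yields class
  probabilities on a six-point grid, which is enough for the corrections to
  beat uncorrected inference by a wide margin but coarser than what a tuned
  k would give; k is exposed as a hyperparameter.
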