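---
title: "Methods: hierarchical Bayesian meta-regression of stimulation design parameters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hierarchical Bayesian meta-regression of stimulation design parameters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stimmeta)
```

## The scientific problem

Transcranial direct current stimulation (tDCS) studies differ in target
region, polarity, intensity (0.25–5 mA in the literature this package is
aimed at), duration (5–30 min), electrode count (2–10), timing relative to
the task, session count (1–20), and experimental design (within- vs.
between-subject). Any of these may moderate the behavioral effect of
stimulation. `stimmeta` treats a corpus of extracted comparisons as a
meta-regression problem: each comparison contributes a signed standardized
mean difference with a known sampling SE, and study-design parameters enter
as moderators.

## Effect sizes

Both design types are converted to Hedges' *g* (small-sample-corrected
standardized mean difference), signed so that positive always means active
stimulation improved behavior — e.g., *faster* reaction times under active
stimulation become positive, higher error rates negative
(`harmonize_sign()`).

* Between-subject: `d = (m1 - m2)/s_pooled`,
  `Var(d) = (n1+n2)/(n1 n2) + d^2/(2 df)`, `df = n1+n2-2`,
  `g = J d` with `J = 1 - 3/(4 df - 1)`.
* Within-subject: primary studies essentially never report the correlation
  between repeated measures, so `r = 0.50` is assumed. The default
  standardizer is the averaged-variance one,
  `s_av = sqrt((s1^2+s2^2)/2)` — at `r = 0.5` and equal SDs this is
  exactly equivalent to averaging the variances, which keeps within- and
  between-subject effects on the same metric — with
  `Var(d) = 2(1-r)(1/n + d^2/(2n))` and `df = n - 1`. The equivalence of
  the two readings ("assume r = 0.5" vs. "average the variances") is exact
  only when the two SDs are equal, so the difference-score alternative
  (`d_z`, standardizer `sqrt(s1^2+s2^2-2 r s1 s2)`) is exposed behind
  `standardizer = "difference"` rather than silently chosen.

Textbooks disagree on variance-formula details (d² vs. g² in the second
term; df vs. N in its denominator); the forms above are fixed and frozen
into the test oracles. For the same reason `metafor`'s `escalc` — which
uses the exact-gamma correction factor and a different variance variant —
serves only as a loose cross-check in the test suite, never as the
implementation.

## Moderator coding

Categorical moderators use sum-to-zero deviation contrasts: each
non-reference level gets an indicator column, the reference row is −1
everywhere, so columns sum to zero across levels and coefficients are
deviations from the grand mean. Columns are labeled
`"Moderator: Level - Reference"`, matching the reporting convention of
meta-regression tables; note that under deviation coding such a coefficient
is the level's deviation from the grand mean, *not* the full A-minus-B mean
difference — the full difference is available exactly as a
posterior-predictive AME (below). The reference defaults to the last
declared level and is configurable per moderator.

Continuous moderators are mean-centered (so the intercept approximates the
grand mean on the coded design, which is what its Normal(0, 1) prior is
calibrated for). Sparse factor levels (default threshold: fewer than 5
effects) are collapsed into user-supplied groups via
`collapse_sparse_levels()`; the package deliberately does not guess
anatomical groupings.

Interaction columns are elementwise products of the *coded* main-effect
columns, and a three-way term always brings its three marginal two-way
products — an interaction-only model without its margins is not
interpretable.

## The model and priors

```
g_i ~ Normal(x_i' beta + u_{study(i)}, se_i^2)
u_s ~ Normal(0, tau^2)
beta_0 ~ Normal(0, 1);  beta_j ~ Normal(0, 2.5);  tau ~ half-Cauchy(0, 0.5)
```

Prior scales are standard deviations (the convention of the major Bayesian
regression packages). Normal(0, 1) on the intercept places ~95.45%
probability on a pooled effect in [−2, 2] — a weakly informative range for
standardized mean differences — while slopes get the wider Normal(0, 2.5)
because there is rarely a strong a-priori guess about how, say, anodal and
cathodal stimulation should differ. The half-Cauchy(0, 0.5) on `tau` is the
standard weakly informative choice for a between-study SD. Because each
effect carries its known sampling SE, observation noise is *not* a free
parameter; a residual SD can be switched on (`estimate_residual_sd = TRUE`,
half-Cauchy(0, 0.5) prior) for sensitivity analyses only. Random slopes are
deliberately not supported: most studies realize only one level of any
given moderator, so study-level slopes are empirically unidentifiable.

## Sampling

Everything Gaussian is conjugate here, so the sampler is a blocked Gibbs
scheme rather than Hamiltonian Monte Carlo:

1. `(beta, u)` drawn *jointly* from the exact multivariate-normal full
   conditional via one Cholesky factorization per iteration. The
   cross-product matrices are precomputed; only the prior-precision
   diagonal changes with `tau`.
2. `tau` updated by slice sampling (stepping-out + shrinkage) on
   `log(tau)` under the half-Cauchy prior.

This removes all step-size tuning and the divergent-transition failure mode
of gradient-based samplers; the analogous sampler-health diagnostic is the
slice-sampler step-out failure count, reported in the fit object and the
run manifest. Defaults are 4 chains × 15,000 iterations with 5,000 warm-up;
the tests run far shorter chains because the Gibbs sampler's effective
sample size per iteration is high for this model class. Initialization is
deterministic (weighted-least-squares `beta`, `u = 0`, `tau = 0.1`), and a
given seed yields bit-identical draws.

In `prior_only` mode the sampler does **not** run Gibbs on the bare prior:
without a likelihood the joint prior factorizes, so `tau` is drawn directly
from its half-Cauchy marginal and `(beta, u)` ancestrally, producing exact
i.i.d. prior draws. (Gibbs on the prior is formally correct but mixes
pathologically in the `tau`–`u` funnel; prior-predictive checks should not
inherit that artifact.)

Convergence is monitored with split-chain R-hat (warning above 1.01),
autocorrelation-based effective sample size via FFT with Geyer's initial
monotone sequence (warning below 400), and MCSE = SD/sqrt(ESS). Constant
chains are flagged undefined rather than erroring.

## Posterior summaries

* **HPD intervals**: shortest contiguous window of the sorted draws holding
  `ceiling(mass * S)` draws; ties broken toward the lowest start. 0.95 by
  default, 0.90 supported for interval plots.
* **Probability of direction**: larger of the fractions of draws above/below
  zero, exact zeros split equally (removes direction bias for any sampler
  with discrete support). Ranges 0.5–1; `pd > 0.95` is roughly analogous to
  a two-sided frequentist p < 0.05.
* **Standardized effects**: per draw, `d = b / sqrt(sigma_res^2 + tau^2)`.
  With the residual SD fixed at zero (the default model), the denominator
  is `tau` alone — this is what reproduces published `d = b / sigma_StudyID`
  arithmetic, e.g. 1.11/0.82 → 1.35. Substituting the mean known sampling
  variance for the residual term is available as a sensitivity option. `d`
  is computed per draw and then summarized (median/HPD), not as a ratio of
  medians; at 2-decimal reporting precision the two agree.
* **Bayesian R²**: per draw, `V_fix` = variance of the linear predictor
  across observations, `V_ran = tau^2`, `V_res` = mean squared sampling SE;
  marginal = `V_fix / total`, conditional = `(V_fix + V_ran) / total`. The
  per-draw marginal value can never exceed the conditional one — published
  tables produced by other estimators occasionally violate this ordering,
  which this implementation treats as a quirk of those estimators and does
  not reproduce.

## Average marginal effects

For a contrast between two factor levels, every observed row is recoded to
level A (and then level B), the expected effect size is computed per
posterior draw, averaged over rows, and differenced. Marginalization is
over the *observed* covariate rows (the standard AME definition), not a
balanced grid. Study intercepts enter both counterfactual predictions
identically and cancel exactly, and sampling noise `se_i` is not re-added:
the AME is a difference of *expected* effect sizes, so its interval
reflects uncertainty about the population-level surface only. In a purely
additive model the AME collapses exactly, draw by draw, to the
corresponding coded-coefficient contrast — this identity is one of the test
suite's oracles. AMEs are only defined for categorical moderators; for
continuous ones the slope is already the quantity of interest.

## Model comparison

`psis_loo()` implements Pareto-smoothed importance sampling leave-one-out
cross-validation: per observation, raw importance ratios `1/p(y_i|theta_s)`
have their `M = min(0.2 S, 3 sqrt(S))` largest values replaced by expected
order statistics of a generalized Pareto distribution fitted to the
exceedances (Zhang–Stephens profile-likelihood quadrature estimator, with
the standard 10-pseudo-observation shrinkage of the shape toward 0.5),
truncated at the raw maximum. Observations with tail shape `k-hat > 0.7`
are flagged unreliable. Model pairs are compared by the paired ELPD
difference, its SE `sqrt(N var(diff))`, and their ratio, with |ratio| > 2
the conventional liberal criterion.

`enumerate_candidates()` + `run_sweep()` reproduce the exhaustive-sweep
design: from a `p`-moderator additive base model, all `choose(p, 2)`
single-two-way-interaction models or all `choose(p, 3)` three-way models
(each with its marginal two-ways) — 28 and 56 for the 8-moderator
domain-general set. Each candidate is fitted under a seed derived from the
master seed and its index, ranked by ELPD (non-converged candidates are
excluded from ranking but reported), and tabulated against both the best
model and the base model.

## The synthetic-data generator

Because extracted meta-analytic corpora are rarely redistributable, the
generator is a first-class module: it defines the conditions under which
every calibration claim in the test suite is made.

* Default scale: 100 studies, 5–9 effects each (~7 on average, matching a
  721-effect / 106-study corpus), `tau = 0.4`, per-arm n of 10–40.
* Moderators are **study-level** draws: categorical levels uniform;
  intensity uniform on 0.25–5 mA; duration uniform on 5–30 min; sessions
  geometric-skewed toward single-session designs (capped at 20); electrode
  counts {2, 4, 8, 10} with 70% mass on conventional two-electrode
  montages. These ranges are the observed ranges of the motivating
  literature; the skews reflect its reported level frequencies.
* Sampling SEs are derived from the Hedges' g variance formula at the
  simulated group sizes and designs, then `g_i ~ N(theta_i, se_i^2)`.
* `simulate_raw_groups()` additionally emits group means/SDs/n (unit SDs,
  control mean 0, active mean set to the uncorrected d implied by the
  target g; a configurable fraction of rows flagged lower-is-better with
  negated raw differences) so the effect-size stage is exercised end to
  end: running `compute_effect_sizes()` on its output reproduces the
  intended signed g to numerical precision.

What the generator does *not* emulate: correlated moderator configurations
across the literature (e.g., particular targets co-occurring with
particular domains), unbalanced level frequencies beyond the two skews
above, non-Gaussian heterogeneity, publication bias, and extraction error
from digitized figures. Passing calibration tests on this generator
therefore demonstrates correctness of the machinery under the model's own
assumptions, not robustness of the substantive conclusions one might draw
from real, messier corpora. Because moderators are study-level, part of
any interaction signal is absorbed by the random intercepts — detecting
interactions in the sweep requires larger corpora than detecting main
effects, which the test suite's detection scenario reflects.

## Numerical choices and degenerate inputs

* `tau <= 0` is a rejected state (−Inf log posterior), not an exception;
  constant MCMC chains yield NA diagnostics with a warning; a degenerate
  (constant) importance-weight tail is flagged with an infinite shape
  rather than smoothed.
* Both group SDs zero → explicit error (no standardizer); |r| ≥ 1 → error.
* Rank-deficient designs warn and proceed (the posterior stays proper
  through the priors); unseen factor levels are errors naming the level.
* HPD ties (all windows equal width, as with uniform draws) resolve to the
  lowest starting index, making results deterministic.
* Same seed + same configuration → bit-identical draws. Permuting input
  rows changes floating-point summation order (~1e-15), which the slice
  sampler's threshold comparisons can amplify into a different but equally
  valid RNG trajectory; row order therefore affects results only at Monte
  Carlo error, which is how the exchangeability test asserts it.

## Problem sizes used in the test suite

Calibration checks run at: 50 replicates of the default 100-study scenario
with 4 × 2,000-iteration chains (interval coverage and pd calibration;
coverage of 95% HPD intervals is accepted within binomial error of the
nominal rate); 20 replicates of a 30-study, 3-moderator scenario for sweep
calibration under an additive truth; an 8-effect conjugate model for the
exact-LOO comparison (PSIS vs. brute-force refits); and a 20-effect
fixed-`tau` dataset for the conjugate-posterior oracle. These sizes give
each check enough resolution to fail informatively while keeping the whole
suite fast enough to run routinely.

## Known limitations

* No Hamiltonian Monte Carlo, no random slopes, no non-Gaussian
  likelihoods, no Bayes factors, no WAIC/k-fold CV, and no
  moment-matching rescue for high-k-hat observations.
* The within-subject SE formula is one defensible reading of an
  underdetermined convention (see Effect sizes); analysts with access to
  raw correlations should supply them via `within_correlation`.
* AMEs marginalize over observed rows; no balanced-grid or reweighted
  variants.
* The sweep refits every candidate from scratch; at published scale
  (57-model three-way sweeps at full chain lengths) this is an
  overnight-class computation, though each model is independent and
  trivially parallelizable across processes.
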