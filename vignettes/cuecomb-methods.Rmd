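---
title: "Models and methods behind cuecomb"
author: "cuecomb authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cuecomb}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cuecomb)
```

## The scientific setting

`cuecomb` implements a complete analysis pipeline for two-interval
forced-choice (2IFC) depth-discrimination experiments that probe how
observers combine redundant sensory cues — binocular disparity, relative
size, and a newly learned audio (pitch) cue. Each trial presents a reference
stimulus (normalized depth 0) and a comparison stimulus at one of 14 signed
levels ±{0.10, 0.25, 0.40, 0.55, 0.70, 0.85, 1.00} (normalized so that ±1
spans ±10 cm of physical depth), and the observer reports which interval
appeared further. Sensory conditions are labelled by their cues: `D`, `S`,
`A` single cues, `Du` the uncertainty-degraded disparity variant, `DS`/`DA`
congruent pairs, `DS+`/`DS-` (etc.) cue-conflict blocks, and `DSi`/`DAi`
incongruent-mapping blocks.

Three markers of cue combination are quantified per observer:

* **Combination index** `CI = min(sigma_D, sigma_2) - sigma_bimodal`:
  positive when two cues are discriminated more precisely than the better
  single cue. Under reliability-weighted (maximum-likelihood) averaging the
  bimodal noise should reach
  `sigma_opt = sqrt(sigma_1^2 sigma_2^2 / (sigma_1^2 + sigma_2^2))`.
* **Re-weighting index** `RI = w_emp(normal) - w_emp(noisy disparity)`:
  positive when the disparity weight drops once disparity is degraded.
  Empirical weights come from cue-conflict blocks: a conflict of
  ±1.5 JND applied to the non-disparity cue of the reference shifts the
  point of subjective equality (PSE) by `(1 - w_D) * delta`, so
  `w_emp = 1 - mu_PSE / delta` with `mu_PSE = (PSE_plus - PSE_minus) / 2`
  (the signed half-difference cancels conflict-independent bias).
* **Incongruence-sensitivity index** `IS = sigma_incongruent -
  sigma_congruent`: positive when reversing the learned cue mapping costs
  precision, as fusion predicts.

## Generative observer models

`observer_profile()` specifies single-cue noises (standard deviation of one
interval's internal estimate, normalized units), a lapse rate, and a
perceptual-decisional strategy. Every strategy reduces to a small mixture of
Gaussian *decision branches* — per trial, the observer compares two internal
estimates, so the response probability is a cumulative normal in the percept
difference with spread `sigma * sqrt(2)`:

* *optimal averaging*: one branch with inverse-variance weights
  `w_D = sigma_other^2 / (sigma_D^2 + sigma_other^2)` and the
  maximum-likelihood fused noise; in conflict blocks the reference percept
  shifts by `(1 - w_D) * delta`, in incongruent blocks the comparison's
  effective slope becomes `2 w_D - 1` (so fusion loses precision);
* *best single cue*: one branch using the lower-noise cue only (immune to
  incongruence when disparity is the better cue);
* *switching*: one cue per trial, by default with reliability-proportional
  probabilities — it mimics re-weighting but yields no precision benefit,
  because the response mixture is flatter than the best cue's own
  psychometric function.

`response_prob()` is the closed form; `percept_sample()` draws the same
model trial by trial, and the two are held together by a Monte-Carlo
agreement test. A `binds_novel_cue = FALSE` observer treats the audio
pairing as best-single-cue regardless of strategy, which represents a causal
inference belief that the novel cue does not share a source with disparity.

**Lapses.** The fitted psychometric function is, as in the study's
formulation, `psi(x) = lambda + (1 - lambda) * Phi(beta (x - alpha))`, whose
asymptotes are `lambda` and 1: a lapse is a stimulus-independent *"further"*
response in the comparison-relative frame. The simulator generates lapses
the same way by default, so the generative and fitted models agree exactly;
the field's more common symmetric guessing convention (asymptotes
`lambda/2`, `1 - lambda/2`) is available everywhere via
`lapse_convention = "guess"`. Because raw button presses are recorded
against interval order ("second interval further"), trial tables carry an
`order` column and analysis recodes responses to the comparison-relative
frame; fits are invariant to consistent relabelling, which is under test.

**Easy trials.** 4% of trials pair the two most extreme depths as attention
catches. They are generated and flagged, and excluded from fits by default
(the estimation target is the main method-of-constants block; a toggle is
provided).

**The degraded-disparity variant (`Du`)** is modelled as a multiplicative
noise inflation (default x2) of `sigma_D`. The physical manipulation
(per-dot disparity jitter) maps onto an observer-level noise increase in a
display-specific way that is not recoverable from first principles, so the
factor is an explicit, configurable model parameter rather than a derived
quantity.

**Population structure.** `simulate_study()` draws per-observer noise
parameters around population means with a between-observer spread and
re-perturbs them per session with a within-observer spread (both on the
natural scale, floored at a small positive value; spreads are small relative
to the means so the truncation is immaterial). This produces exactly the
variance structure the repeatability analysis partitions. Audio mapping
direction is counterbalanced; every stochastic entry point takes an explicit
seed, and study-scale generation uses one master seed with deterministic
per-participant substreams.

## Two-stage Bayesian psychometric fitting

Fitting is Bayesian with uniform priors over stated ranges, summarised by
posterior means over dense parameter grids:

* PSE `alpha`: fixed at 0 wherever a shift would be meaningless (noise
  estimation), free on `[-1, 1]` in conflict conditions;
* slope `beta`: positive, uniform on (0.05, 200] — a sensory-noise floor of
  about 0.0035 normalized units; the grid is log-spaced and cell widths are
  used as prior weights, so the prior is uniform on the continuous interval;
* lapse `lambda`: uniform on [0, 0.2].

Stage 1 estimates one lapse per participant x session jointly across that
session's conditions, integrating each condition's slope (and PSE where
free) out against its prior; the shared-lapse posterior is the product of
the per-condition marginals. Stage 2 refits each condition with the lapse
fixed at the stage-1 value. Fixing the lapse removes the lapse-slope
trade-off from the per-condition fits; the package's tests verify directly
that fixing `lambda` at its generative value lowers the slope's RMSE
relative to a per-condition free lapse.

Numerical choices: the log-likelihood tables over (level, `alpha`, `beta`,
`lambda`) depend only on the design and the grids, so they are precomputed
and cached; a fit is then one matrix product per lapse node, and the hot
path (the lapse-marginalised three-parameter fit used in power simulations)
is a small C++ kernel. The lapse integral uses an 11-node trapezoid rule
(results are identical to 41 nodes to four decimals); stage-2 lapse values
are snapped to the lapse grid (0.005 resolution). Posterior means are stable
under grid refinement (halving the spacing moves slopes by well under 1%, a
tested property). Degenerate inputs are never fitted silently: fewer than 20
usable trials is an error, all-identical responses are flagged, and
separable data — where the likelihood cannot bound the slope from above —
are flagged when most posterior mass sits in the upper half of the slope
range.

Sensory noise derives from the slope as `sigma = 1/(beta * sqrt(2))`
(a 2IFC response compares two noisy estimates) and `JND = sigma * sqrt(2)`.
The posterior-mean point estimate carries a modest downward bias in `sigma`
(the posterior over `beta` is right-skewed under the wide uniform prior);
at study-like noises the median absolute relative error at 168 trials is
11-16%, within the 20% the pipeline's recovery tests require.

## Group analysis

Exclusions mirror the study's rules: participants whose session lapse
estimates average ≥ 0.10 are removed everywhere (the source text is
ambiguous between mean/median across sessions; the mean is used);
disparity-noise outliers beyond `median ± 2.5 IQR` are removed everywhere,
size/audio-noise and weight outliers only from their cue pair; observers
whose raw audio-condition responses anti-correlate with depth ("inverse
mapping") are removed from the audio pair. The fence is two-sided as
stated, and a zero-IQR group excludes nobody. Because the Bayesian fits
constrain slopes positive, inverse mapping is detected from the raw
responses (Spearman sign), not from a signed fitted slope.

Hypothesis tests are two-tailed Wilcoxon signed-rank tests (exact for small
samples without ties, normal approximation with continuity correction
otherwise — the mainstream default, matched against exhaustive enumeration
of the null in the tests); zero differences are dropped by Wilcoxon's
convention and an all-zero comparison is reported as V = 0, p = 1.
Classification counts (marker present = index > 0) are compared between cue
pairs with McNemar's continuity-corrected chi-square on the discordant
cells — the variant that reproduces the published worked example
(22 vs 6 discordant: chi-square 8.04) — reported as undefined when there are
no discordant pairs. The nuisance-cue control (does holding a constant
second cue inflate single-cue noise estimates?) uses a one-sided test —
signed-rank by default, since the design is within-observer, with a
rank-sum option — plus a default-prior JZS Bayes factor for the null on the
paired differences (Cauchy scale `sqrt(2)/2`, configurable), implemented by
quadrature and verified against an independent implementation.

## Repeatability

`fit_repeatability()` fits the Gaussian random-intercept model
`value ~ 1 + (1 | participant)` by REML (lme4) and reports
`R = sigma_G^2 / (sigma_G^2 + sigma_R^2)`. Uncertainty comes from a
parametric bootstrap (simulate from the fitted model, refit); significance
from a likelihood-ratio test against the no-random-effect model with the
boundary-corrected 50:50 mixture of a point mass at zero and chi-square(1)
as reference, and optionally from a permutation test that shuffles
observations across observers. On balanced data the REML solution equals
the one-way ANOVA intraclass correlation, so bootstrap and permutation
refits use that closed form there (vectorised over thousands of resamples;
equality with lme4 is asserted to 1e-6 in the tests); unbalanced data fall
back to lme4 refits. Variance estimates at the zero boundary yield R = 0
with a flag, and singular fits are marked non-converged rather than
silently reported — the report separates converged from all fits.

## Simulation-based power

`simulate_power_cell()` estimates the probability of detecting a
group-level combination benefit: each simulated experiment draws `n`
observers with best-cue noise `sigma_best`, worst/best ratio `noise_ratio`
and lapse uniform on [0, 0.10]; generates 168 2IFC trials per condition
(best, worst, and optimally combined — the maximum-likelihood prediction)
per observer; fits every condition; and applies the two-tailed Wilcoxon
signed-rank test of combined vs best single-cue sensory noise, with the
best cue measured empirically as the minimum of the two fitted single-cue
noises, exactly as the combination index defines it. Power is the fraction
of experiments significant at 0.05 in the combination direction.

Two design choices deserve emphasis, both genuinely open and both resolved
by explicit reasoning rather than convention:

* **Per-condition fits, not shared lapse.** Sharing one lapse across the
  three conditions of an observer *correlates* their estimation errors;
  correlated errors cancel in the paired test, which raises simulated power
  far above what independent per-condition fits give. Power estimates are
  meant to anticipate an analysis whose comparisons are dominated by
  independent per-condition measurement error, so the power module defaults
  to the single-stage three-parameter fit (PSE, slope, lapse all free under
  their uniform priors, marginal posterior means) — the standard Bayesian
  psychometric fit — and exposes `fit = "two-stage"` for sensitivity
  analysis. With the default, a 30-observer, ratio-1.5 cell lands at ~80%
  power; the two-stage variant puts the same cell in the mid-90s.
* **Fixed cell parameters.** All observers in a cell share the cell's
  `sigma_best` and ratio (`population = "fixed"`); a log-normal jitter
  around the cell value (`population = "jittered"`, CV configurable) is
  available. Simulated power is far more sensitive to the fitting noise
  than to moderate population heterogeneity.

Under the null (`combination = "none"`, best-single-cue followers) the
rejection rate is at or below the nominal 0.05: exactly nominal with the
`assigned-best` comparator, conservative with the default empirical-minimum
comparator, whose downward bias protects against spurious combination
claims. Power is monotone: nonincreasing in the noise ratio and in
`sigma_best`, nondecreasing in `n` (tested within Monte-Carlo slack).

## Problem sizes and what the tests do and do not show

The packaged tests run scaled-down versions of every stochastic check
(hundreds of replicate studies, hundreds of bootstrap resamples,
1000-experiment power cells), sizes chosen for tight-enough Monte-Carlo
error on each assertion. The synthetic generator emulates the study's
structure — noise levels, strategy mixtures, lapse ranges, conflict scaling,
session variance structure — but real data add features it does not model:
serial dependencies and learning within blocks, non-stationary lapsing,
stimulus-specific artifacts, and individual deviations from any of the three
idealized strategies. Passing tests therefore certify the pipeline's
statistical machinery and its calibration on model-faithful data, not the
truth of the observer model for any particular dataset.

## Known limitations

* The posterior-mean summary under a wide uniform slope prior shrinks
  `sigma` by ~10-15% at 168 trials; comparisons between conditions (the
  markers) are differences of equally-biased quantities, which largely
  cancels the effect, but absolute noise values inherit it.
* Repeatability assumes a Gaussian measure (a log transform is provided
  for noise values); link-scale repeatability for non-Gaussian measures is
  out of scope.
* The power module covers the combination benefit only — re-weighting and
  incongruence markers have no power analysis, matching the pipeline's
  scope.
* Alternative combination models (e.g., intrinsic-constraint) and full
  causal-inference model fitting are deliberately out of scope.
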