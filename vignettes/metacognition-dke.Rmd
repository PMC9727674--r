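---
title: "Measuring metacognition and dissecting the Dunning-Kruger effect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring metacognition and dissecting the Dunning-Kruger effect}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metadke)
```

## The problem

In many tasks the least skilled people overestimate themselves the most —
the Dunning–Kruger effect (DKE). The classical explanation is a *dual
burden*: the same resources are needed to perform and to judge one's
performance, so the unskilled both fail and fail to notice. The rival
*noise-plus-bias* explanation needs no metacognitive deficit at all:
global self-estimates are noisy and regress toward a common, typically
optimistic default, so subtracting true performance mechanically produces
overestimation at the bottom and underestimation at the top.

Separating these accounts requires *measuring* metacognition properly,
trial by trial, rather than reading it off one-shot global estimates.
This package implements that measurement model, the surrounding study
pipeline, and a generative simulator in which the ground truth is known —
so the artefactual route to a DKE can be demonstrated directly.

## The measurement model

### Type-1 (cognitive) level

Each two-alternative trial is modelled by equal-variance signal detection:
evidence is unit-variance normal with mean −d′/2 (class 0) or +d′/2
(class 1); a criterion *c* turns evidence into a response. From the hit
and false-alarm rates, `fit_type1()` computes d′ = z(H) − z(FA) and
c = −½(z(H) + z(FA)).

Rates of exactly 0 or 1 would make these infinite. The maximum-likelihood
path applies the conventional 1/(2N) edge correction; the Bayesian path
needs none, but anchors on the corrected point estimates as fixed type-1
parameters (only confidence is modelled at the second level).

### Type-2 (metacognitive) level

The K = 4 confidence ratings are modelled by a *meta observer* that
re-reads the evidence axis with its own sensitivity, meta-d′: the type-1
sensitivity an ideal rater would need to produce the observed ratings.
Its criterion is the type-1 criterion rescaled, c′ = c·meta-d′/d′, and
K − 1 response-specific thresholds on each side of c′ carve the axis into
confidence bins. Cell probabilities are normal-CDF differences over those
bins; the likelihood is multinomial in the *conditional* probabilities
P(conf | stim, resp), one factor per trial. A single meta-d′ spans both
response classes (non-response-conditional estimation).

Three quantities summarise metacognition:

* **sensitivity** — meta-d′ itself, in d′ units;
* **efficiency** — meta-d′/d′, the fraction of first-order information
  exploited (1 for an ideal observer);
* **bias** — the unweighted mean of mean-confidence-given-correct and
  mean-confidence-given-incorrect. The unweighted form matters: a pooled
  mean rewards accuracy, whereas this measure isolates scale use.

### Estimators

`fit_meta_d_mle()` maximises the likelihood over meta-d′ and the 2(K−1)
thresholds. Thresholds are parameterised as log-increments away from c′,
which enforces their ordering by construction; optimisation is BFGS from
data-driven starting values (threshold starts from inverse-normal
exceedance rates of the observed ratings), with a Nelder–Mead fallback if
BFGS fails to converge. Degenerate data (a single rating level used) are
flagged `unidentified` rather than silently fitted.

`fit_meta_d_bayes()` samples the posterior with JAGS. The prior on
meta-d′ is Normal(mean = observed d′, variance = 2); priors on the
threshold log-increments are Normal(0, sd 2), weakly informative and
ordering-preserving. Three chains of 10 000 retained samples follow a
1 000-sample burn-in (all configurable); convergence is summarised by the
Gelman–Rubin statistic with a 1.05 flag threshold, and a non-converged
fit is returned flagged, not discarded. Chains are seeded derivedly, so a
fit is exactly reproducible from its seed. With an empty count tensor the
posterior is the prior and is sampled directly. Efficiency on this path
is the posterior mean of meta-d′/d′ with d′ fixed — whether the original
toolbox also treats d′ as fixed in that ratio is ambiguous, so this
choice is documented rather than assumed; with fixed d′ it equals the
posterior-mean ratio.

Because the exact threshold priors and sampler tuning of the original
Matlab toolbox are not public in detail, numerical agreement with it is
approximate by construction; the two estimators in this package agree
with each other within Monte Carlo error on large samples, and both
satisfy the ideal-observer identity (meta-d′ → d′ when confidence is read
from the same evidence as the response).

## Study measures, screening, associations

Raw accuracies are remapped to 0–100 scores ((raw − 50) × 2). Percentile
ranks use the Hazen convention, 100·(rank − 0.5)/N with mean ties —
symmetric, never pinning anyone to 0 or 100, and consistent with a 1–100
estimate scale; ranks are assigned over *all* participants before any
exclusion, because they define the standing against which relative
estimates are scored. Estimation errors are plain subtractions (estimate
minus actual), positive = overestimation.

Floor/ceiling screening excludes raw accuracy ≤ 50% or = 100% in either
phase (when both phases trigger, the baseline reason is reported first).
Efficiency — a ratio that explodes when d′ is small — additionally gets a
conservative 2-IQR fence with type-7 quartiles, so the fence is exactly
reproducible.

Correlations report Spearman (primary) and Pearson coefficients with
percentile bootstrap 95% CIs resampling participants (default 10 000
resamples, seed logged; the resample count is a package default, as the
original analyses state only that CIs were bootstrapped). P-values use
the t approximation with n − 2 degrees of freedom, which is standard at
n ≈ 150. `fisher_ci()` and `correlation_power()` provide the Fisher-z
planning calculations; note that published required-n figures from other
power software can differ by a few participants from the closed form used
here (documented in `?correlation_required_n`), so no attempt is made to
match any particular calculator.

## The path model

The a-priori model routes the skill–error association entirely through
four mediators measured in the test phase — performance, metacognitive
sensitivity, efficiency and bias — with free mediator residual
covariances and *no* direct skill → error path. With six observed
variables this leaves exactly one degree of freedom, matching the χ²(1)
statistics of the study the design mirrors; a `direct = TRUE` switch
saturates the model for sensitivity analyses. Analysis data are
rank-transformed then z-scored, so coefficients are standardised and
robust to monotone distortions.

For this recursive structure, full-information ML factorises into
equation-wise least squares, which is what `fit_path_model()` computes;
the log-likelihood and AIC come from the implied multivariate-normal
covariance structure. Indirect effects are a·b products; the total effect
is identically their sum. Inference is by participant-resampling
percentile bootstrap (default 5 000 resamples); robust scaled test
statistics are out of scope — point estimation plus bootstrap intervals
carry the inference.

`reduce_model()` implements the pre-registered-style reduction: mediators
whose indirect-effect CI includes zero are candidates; each single-drop
reduction is fitted; the lowest-AIC candidate is accepted if it lowers
the AIC; significant paths are never dropped. Ties break by fewer
parameters, then by the fixed mediator order. Dropping a path removes the
mediator *variable* from the model, so successive models are compared
across their own variable sets — the only reading consistent with the
published AIC gaps of thousands between nested-looking models, since a
dropped variable takes its marginal likelihood contribution with it.
`compare_models()` turns ΔAIC into exp(ΔAIC/2), capped at the largest
representable double (flagged when capped).

## The synthetic cohort

`cohort_config()` defaults encode the emulated study design:

| parameter | default | rationale |
|---|---|---|
| baseline / test trials | 48 / 90 | the emulated two-phase design |
| latent skill d′ | TruncNormal(1.0, 0.6, floor 0) | baseline accuracy mostly 55–85%, a few floor/ceiling cases to exercise screening |
| practice gain | +0.5 d′ | a visible baseline→test benefit that preserves rank order |
| efficiency profile | constant 0.8 | typical empirical efficiency; constant across skill so *no* metacognitive deficit exists by construction |
| confidence thresholds | c′ ± (0.5, 1.0, 1.5) | symmetric, all four levels used at typical d′ |
| self-estimate weight w | 0.3 | puts estimate–performance correlations near the 0.4–0.5 typically observed |
| relative anchor | 58 | the better-than-average effect: mean relative self-estimates sit above 50 |
| absolute anchor | 62 | above mid-scale yet pessimistic relative to typical test scores, the configuration that flips the asymmetry |
| estimate noise sd | 15 | with w = 0.3, yields realistic error spreads |

The self-estimate noise and weight are free parameters chosen to
reproduce the qualitative pattern — they are emulation choices, not
estimates of any dataset.

Confidence is generated, by default, from the meta-observer conditional
multinomial, so the generative model *is* the fitted model and recovery
tests are sharp. An alternative evidence-route generator bins a noisy
copy of the very evidence sample that produced the response; with zero
noise it is the ideal observer (meta-d′ = d′), and added noise degrades
meta-d′ monotonically — the robustness check that the estimators respond
to genuine metacognitive signal, not to the generator's algebra.

What the generator does *not* emulate: item-level difficulty structure,
response times, sequential effects (practice arrives as a single step,
not a drift), integer-snapped estimate scales, and any genuine
skill–efficiency link (unless configured). Passing tests therefore show
that the pipeline is correct under its own assumptions, not that real
raters satisfy those assumptions.

`demonstrate_noise_plus_bias()` runs the full pipeline on a cohort with
constant efficiency and an optimistic anchor. Across replicate cohorts
the skill–relative-error rank correlation is strongly negative (mean
≈ −0.5), the performance indirect path dominates the metacognitive paths
by far, and the reduction almost always terminates in (or is beaten by)
the performance-only model — a DKE with no metacognitive cause anywhere
in the generator. Because the reduction frequently lands on the
performance-only structure itself, the "performance-only wins" verdict
counts an exact AIC tie between structurally identical models as a win.

## Numerical choices and degenerate inputs

* d′ = 0 participants: c′ is undefined, the meta fit is skipped and the
  participant is flagged (these are typically floor-excluded anyway).
* Zero-probability likelihood cells with positive counts yield −Inf, not
  an error; the optimiser guards them with a large finite penalty.
* Bootstrap resamples with a constant variable are skipped and counted.
* Every stochastic stage derives its seed as a deterministic hash of the
  master seed and the stage name (`derive_seed()`), keeping all seeds in
  the 32-bit range and making any stage independently reproducible.
* JSON reports are written with fixed settings so a repeated run with the
  same master seed is byte-identical.

## Known limitations

* **The efficiency ratio artifact.** meta-d′/d′ shares its denominator
  with d′-hat, so estimation noise induces a small negative
  efficiency–d′ association (about ρ ≈ −0.15 at 90 trials in simulation)
  even when true efficiency is constant. This is the association one
  naturally expects when correlating a measure with a fractional index
  it denominates; it fades with trial count but is not zero at study
  scale. Observed efficiency–performance correlations near zero should
  be read with this artifact in mind.
* **Small-sample meta-d′ noise.** At 90 trials the MLE of meta-d′ is
  heavy-tailed; cohort-mean efficiency carries a modest upward bias
  (≈ +0.02–0.04 at the defaults) from the nonlinearity of the ratio. The
  2-IQR fence removes the worst cases; Bayesian estimation shrinks the
  rest toward d′.
* **Model-comparison scope.** AICs are comparable within this package's
  likelihood convention (covariance structure, no mean parameters);
  comparing against values from other software is meaningful only as
  differences computed within one convention.
* **No hierarchical pooling.** Estimation is strictly single-participant;
  group-level Bayesian pooling is out of scope.

## Problem sizes used by the test suite

The suite exercises: ideal-observer identity at 10⁵ trials (MLE and
MCMC); efficiency recovery on 20 cohorts of 150 participants × 90 trials;
path recovery and CI calibration on 200 replicates of n = 150 with 500
bootstrap resamples; and artifact emergence on 50 replicate cohorts with
reduced bootstrap sizes (500/300). These sizes give Monte Carlo error
comfortably below the asserted tolerances while keeping a full run in the
minutes range on a single CPU.
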