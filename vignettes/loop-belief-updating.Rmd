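---
title: "Modelling valence-biased belief updating in performance-feedback tasks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling valence-biased belief updating in performance-feedback tasks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loopbelief)
```

## The problem

In performance-feedback paradigms of the "learning of own performance"
family, participants repeatedly rate the percentile at which they expect to
perform (EXP, on a 0–100 scale) and then receive rigged percentile feedback
(FB). Two estimation categories are secretly assigned to a High and a Low
Ability condition, so participants gradually learn that they are "good" at
one task and "poor" at the other; in the agent variant they additionally
observe another person receiving feedback (Self vs Other), and in the
audience variant the feedback is given in private or in front of an
observer. The scientific questions are (i) whether trial-by-trial updating
is asymmetric in the valence of the prediction error — learning more from
worse-than-expected than from better-than-expected feedback — (ii) whether
that asymmetry is specific to the self, and (iii) how it co-varies with
self-esteem and social anxiety.

`loopbelief` implements the full pipeline: a generative simulator of the
task, a space of delta-rule learning models, per-subject Bayesian fitting,
PSIS-LOO + random-effects Bayesian model selection, and the group-level
statistics. Because trial-level datasets for such tasks are typically not
public, the simulator is a first-class, tested component: every downstream
stage is exercised against cohorts with known ground truth.

## Feedback schedules and trial designs

Low Ability feedback is delivered as integer percentiles in [1, 60]
distributed around the 35th percentile with SD 16; High Ability feedback in
[40, 99] around the 65th with SD 16. `generate_feedback_schedule()` draws
from a parent normal distribution and rejection-samples into the range —
rejection rather than clipping, so no probability mass piles up at the
bounds — then rounds to whole percentiles, as feedback is displayed to
participants.

One calibration detail matters. A N(35, 16) rejection-truncated to [1, 60]
does *not* deliver mean 35 and SD 16: truncation pulls the realized moments
to 33.7 and 13.4. Since the stated numbers describe the feedback
participants actually receive, the generator solves for the parent (mu,
sigma) whose *truncated* distribution has exactly the target mean and SD
(for the low condition the parent is approximately N(54.9, 37.8); the high
condition is its mirror image). The solution is found once by
moment-matching (`optim` on the closed-form truncated-normal moments) and
cached. The resulting within-range shape is smooth and unimodal but flatter
than a bell; we consider matching the delivered mean/SD/range more faithful
than matching the parent's nominal parameters, because those three numbers
are what constrain the learning problem (the prediction-error magnitudes).

`build_design()` interleaves the conditions (4 cells x 25 trials for the
agent task, 2 x 30 for the audience task) under the constraint that at most
two consecutive trials share a condition, by sequential sampling among
eligible conditions (probability proportional to remaining count) with
restart on dead ends. Real experiments used fixed, unpublished orders; we
generate orders satisfying the published constraints from a seed, which is
the reproducible analogue. Counts whose largest element exceeds
`2 * (others + 1)` are rejected as unsatisfiable.

## The model space

All learners share the delta rule

$$\mathrm{EXP}_{t+1} = \mathrm{EXP}_t + \alpha\,\mathrm{PE}_t,
\qquad \mathrm{PE}_t = \mathrm{FB}_t - \mathrm{EXP}_t,$$

with a separate latent expectation per (agent x ability) condition, and
differ only in which learning-rate slot a trial uses:

| model | rule | slots |
|---|---|---|
| `M1_unity` | one rate | 1 |
| `M2_ability` | one rate per ability condition | 2 |
| `M3_valence` | one rate per PE sign | 2 |
| `M4_unity_SO` / `M5_ability_SO` / `M6_valence_SO` | as above, split by self/other | 2 / 4 / 4 |
| `M_mean` | no learning; fitted constant per condition | 0 (+2 or 4 means) |

The self/other variants exist only for the agent task (7 models); the
audience task compares 4. Initial beliefs are fitted parameters, by default
one per condition (`fitted_per_condition`); one-per-agent
(`fitted_combined`) and fixed-at-first-rating schemes are available.

Two conventions worth making explicit:

* **Latent-state updating.** The published update equations do not say
  whether `EXP_t` on the right-hand side is the model's own expectation or
  the observed rating. We default to the latent-state reading — PEs are
  computed against the model's internal expectation and observed ratings
  are noisy readouts — because it makes simulation and fitting symmetric
  (the fitted model is exactly the generative model). The observed-state
  variant is available via `state = "observed"`.
* **Zero prediction errors** are routed to the positive-valence slot. The
  choice is arbitrary but fixed; with continuous ratings a PE of exactly 0
  has measure zero, and even with integer feedback it is rare.

Observations are modelled as Gaussian around the latent expectation with a
single per-subject `noise_sd`, shared across conditions — the minimal
observation model for continuous ratings; ratings are treated as continuous
on [0, 100] with no discretization of the likelihood. Richer models nest
their parents exactly when parameters are tied (`M6 -> M4 -> M1`), which
the tests assert bit-for-bit.

## Fitting

`fit_subject()` samples the per-subject posterior by component-wise
random-walk Metropolis with reflecting proposals at the parameter bounds.
Per-parameter proposal scales adapt toward a 0.44 acceptance rate during
warmup only, so the post-warmup kernel is a fixed, valid MCMC kernel.
Defaults mirror common practice for this task family: 3 chains, 1000
warmup iterations, 2400 retained draws in total after thinning by 3
(3400 iterations per chain). The inner loop is C++ (Rcpp), so a full fit of
the 9-parameter valence self/other model on 100 trials takes well under a
second.

Priors are weakly informative and scale-appropriate, recorded in
`sampler_config()` for auditability: learning rates uniform on [0, 1],
initial beliefs (and mean-model condition means) normal(50, 20) truncated
to the rating scale, observation noise half-normal(20). The source papers
for such tasks do not report their priors or transforms, so exact numerical
replication of posteriors is not a goal; recovery of generating parameters
and of qualitative contrasts is.

Convergence is monitored with split rank-normalized R-hat and a
Geyer-truncated autocorrelation ESS (`compute_rhat()`, `compute_ess()`),
and `apply_exclusions()` implements the usual rule: a subject is dropped
when any parameter of any fitted model has R-hat > 1.1 (degenerate,
zero-variance chains count as failures). Implausible-parameter screening
(mean learning rate > 10 SD from the cohort mean) only *flags* subjects —
that judgment is left to the analyst.

## Model selection

`psis_loo()` computes approximate leave-one-trial-out expected log
predictive densities from the pointwise log-likelihood matrix. Per trial,
log importance ratios (the negative pointwise log-likelihood) are
stabilized by fitting a generalized Pareto distribution to the largest
`M = min(0.2 S, 3 sqrt(S))` weights (Zhang–Stephens profile posterior-mean
estimator with the usual weak-prior shrinkage of the shape toward 0.5) and
replacing them with its order-statistic quantiles, capped at the raw
maximum. The fitted shape k-hat diagnoses reliability; trials with
k-hat > 0.7 are flagged, and `loo_sensitivity()` re-scores all models with
each subject's flagged trials removed (the union across models, so every
model is scored on the same trials) for a sensitivity re-run of the
selection. The implementation was checked against an exact analytic
leave-one-out on conjugate normal-mean instances, and reduces to the
pointwise log-likelihood for a degenerate (point) posterior, where k-hat is
reported as `-Inf`. `loo_diff()` reports paired differences with the
`sqrt(n * var)` standard error of the pointwise differences.

`bms()` performs random-effects Bayesian model selection on the per-subject
summed PSIS-LOO scores used directly as log model evidence (no additional
complexity penalty — cross-validation already prices complexity). A flat
Dirichlet prior over population model frequencies is updated by the
standard variational iteration (tolerance 1e-8); exceedance probabilities
come from 1e5 Monte-Carlo draws of the Dirichlet posterior (seeded, and
stable to < 0.01 across reruns); the Bayesian omnibus risk is the posterior
probability of the equal-frequency null from the free-energy comparison,
and the protected exceedance probability is
`pxp = (1 - BOR) * xp + BOR / K`.

## Group statistics

The valence bias score `(alpha_pos - alpha_neg) / (alpha_pos + alpha_neg)`
normalizes the updating asymmetry to [-1, 1]; it is scale-invariant, odd
under swapping its arguments, and undefined when both rates are zero (such
subjects are returned as `NA` with a warning and drop out of correlations
listwise). `rm_anova()` wraps `stats::aov` with `Error()` strata — a
split-plot decomposition with subject as the blocking factor, optionally
with a between-subjects factor. Every design this package produces is
balanced, where type-I and type-III sums of squares coincide, so no
additional contrast machinery is needed; 2 x 2 within designs need no
sphericity correction. p values are two-sided throughout and no
multiple-testing correction is applied to these ANOVAs.

`partial_corr()` is the Pearson correlation of residuals after linear
removal of the controls (used, e.g., to relate bias scores to final
expectation ratings controlling for initial ones), and
`fisher_z_compare()` contrasts two independent correlations. `ppc()`
quantifies, per subject and condition, the variance in observed ratings
captured by the fitted model's predicted trajectory (regression R²;
constant predictions get R² = 0 and a flag) and repeats the model-free
Trial x condition ANOVA on the predictions, checking that the winning
model reproduces the design's core effects and not merely the likelihood.

## The synthetic cohort and what it does (not) emulate

`simulate_cohort()` draws per-subject true learning rates from Beta
distributions (method-of-moments shapes). The default population centres
the valence self/other rates at 0.12/0.14 (self, positive/negative PE) and
0.11/0.10 (other) with SDs 0.06–0.09 — values on the scale typically
recovered in this paradigm — the audience default at 0.07/0.10. Initial
beliefs are truncated-normal(50, 10), reflecting the design assumption that
participants start near the 50th percentile, and observation noise defaults
to 10 rating points. Trait scores are generated through a Gaussian copula
on the *true* self valence bias score: self-esteem on an SDQ-III-like
scale (100 +- 15) with default coupling +0.44, social anxiety on a
SIAS-like scale (25 +- 13, floored at 0) with default coupling -0.39. Only
the correlation structure, not the questionnaire marginals, matters for
recovery tests. True parameters are returned for recovery studies;
`write_cohort()` exports data, traits and ground truth as CSV/JSON.

The simulator deliberately omits several features of real data: feedback
orders are seeded random draws under the published constraints rather than
the (unpublished) fixed orders, which may have balanced PE valence in ways
a random order does not; ratings have homoscedastic Gaussian noise with no
anchoring, rounding to multiples of 5, drift, or reaction-time structure;
the "other" agent's feedback is scheduled identically to the self's rather
than modelling a real co-actor; and trait marginals are synthetic. Passing
recovery tests therefore show that the *pipeline* is correct and
well-calibrated under its own assumptions — not that those assumptions
exhaust real behavior.

## Numerical choices and degenerate inputs

* Feedback calibration: moment-matching tolerance 1e-6 on the squared
  moment error; values rounded to integers after rejection sampling.
* Sampler: reflection keeps proposals in bounds without Jacobians; the
  noise scale is bounded below at 1e-3; adaptation window 50 iterations,
  scales clamped to [1e-4, 50].
* R-hat is `NA` (and treated as an exclusion) for zero-variance chains;
  ESS is 0 for constant chains and capped for antithetic chains.
* PSIS: near-uniform ratio vectors skip smoothing with k-hat `-Inf`;
  non-finite log-likelihoods are an error naming the trial.
* BMS: variational tolerance 1e-8, max 1000 iterations; ties in the
  Monte-Carlo argmax are broken at random.
* `rm_anova()` reports effects with zero effect-and-error variance as
  F = 0, p = 1 with an explanatory note rather than NaN.

## Simulation-study sizes

The shipped tests run, among others: parameter recovery on 20 simulated
subjects of the valence self/other model; model recovery on 15-subject
cohorts generated from the unity, valence, and valence-self/other models
across 5 seeds with the full 7-model comparison (600 Dirichlet draws for
the exceedance check); and a 5-seed, 25-subject end-to-end check that the
Agent x PE-Valence interaction retains the self-specific negativity-bias
direction at generating rates of 0.12/0.14 (self) and 0.11/0.10 (other).
These sizes keep the whole suite comfortably fast at reduced draw counts
(2 chains, 250–500 warmup, 500–1000 retained draws) while leaving the
qualitative conclusions stable; the package defaults remain the fuller
3 x 3400-iteration protocol.

## Known limitations

* **Boundary shrinkage of posterior means.** With learning rates bounded in
  [0, 1], uniform priors, and realistic data volumes (~25 informative
  trials per rate slot at noise 10), the posterior mean of a near-zero
  learning rate is biased upward by roughly +0.02 to +0.07 per slot — a
  property of the Bayes estimate itself, which we verified against exact
  grid quadrature, not of the sampler. Group-mean learning rates from small
  cohorts inherit this bias; the valence *bias score* is more robust
  because both rates shrink in the same direction. Analysts who need
  unbiased group means should use more trials, the posterior median
  (`central = "median"`), or informative priors.
* One observation-noise scale per subject, shared across conditions.
* No hierarchical pooling across subjects (matching per-subject fitting
  practice for this task family); each subject x model fit is independent.
* PSIS-LOO assumes conditionally independent trials given parameters; the
  latent-state trajectory makes trials *sequentially* dependent through the
  state, so "leave one trial out" means leaving out its likelihood
  contribution, not re-simulating the trajectory without it. This matches
  standard usage but is worth keeping in mind when k-hat flags trials.
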