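---
title: "Offline reinforcement learning for ventilator settings: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Offline reinforcement learning for ventilator settings: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ventrl)
```

## The decision problem

Mechanically ventilated ICU patients are re-evaluated every few hours: the
clinician chooses a set tidal volume (Vt, indexed per kg of ideal body
weight), a positive end-expiratory pressure (PEEP) and an inspired oxygen
fraction (FiO2). Suboptimal combinations contribute to ventilator-induced
lung injury; the long-term outcome of interest is 90-day or in-hospital
mortality. ventrl casts this sequential problem as a finite Markov decision
process (MDP) learned entirely offline from observational trajectories:

* **States** `S`: the patient's condition in each 4-hour bin, summarized by
  a 44-feature "data fingerprint" (vitals, labs, fluid balance, Glasgow
  Coma Scale) and discretized by k-means into `k` clusters (default 650),
  plus two absorbing terminal states -- survival and death -- appended
  after the physiologic states. Whether terminal states are counted inside
  or on top of the published 650 is ambiguous; here they are two
  *additional* states.
* **Actions** `A`: the 3-dimensional ventilator-setting grid with 7
  half-open bins per dimension (`[lower, upper)`, last bin open-ended),
  343 flat actions. There is deliberately no "no action" option: every
  decision instance carries an active setting.
* **Transitions** `T(s, a, s')`: maximum-likelihood counts
  `N(s, a, s') / N(s, a)`, held sparsely as an `(S*A) x S` matrix.
* **Rewards**: +100 on the transition into survival, -100 into death, 0
  elsewhere. The three-dimensional reward `R(s, s', a)` is collapsed to
  `R(s, a)` by multiplying with `T` and summing over `s'`.
* **Discount** `gamma`: defined but never printed in the source material;
  the default is 0.99, configurable via `load_config(gamma = ...)`.

## Preprocessing

Events are defined from raw binned stays by the cohort rules: a documented
set tidal volume opens a ventilation event (guaranteeing volume-controlled
ventilation); any of the three settings documented within two sample
periods (8 h) continues it; extubation, non-invasive ventilation or
supplemental oxygen ends it. Inclusion requires age over 18, no treatment
withdrawal in the window, a documented outcome, and at least 24 h (six
post-onset bins); only the first qualifying event per stay is kept, clipped
to one pre-onset bin plus 18 post-onset bins (-4 h to +72 h). The
"supplemental oxygen" terminator is applied literally to the event flag,
not to arbitrary oxygen-therapy records.

Missing features are handled in a fixed order, each stage a documented
choice where the underlying procedure was named but not parameterized:

1. **Outlier removal first** (Tukey fences, multiplier 1.5), so that held
   values are never outliers. The optional "90% empirical interval"
   frequency filter is a second mask, off by default, because how the two
   filters compose is not specified.
2. **Sample-and-hold** with per-feature hold limits set to the median
   inter-measurement gap (in bins) pooled across stays -- the "frequency
   analysis" made concrete. Features observed fewer than twice fall back
   to 2 bins, the event-continuation horizon.
3. **Discard** events still missing more than 50% of their feature cells.
4. **Imputation** of the remaining gaps: k-nearest-neighbour over z-scored
   rows (k = 3, Euclidean distance on co-observed coordinates, column-mean
   fallback), with an iterative truncated-SVD completion
   (rank `min(10, floor(d/4))`, tolerance 1e-4, 50 iterations) and plain
   column means as configured alternatives. For cohort-scale data the kNN
   search uses a deterministic donor subsample (default 2000 rows), a
   scalability choice that bounds the search at O(n * pool).

A missing-data diagnostic tests each feature's missingness indicator
against the observed values of every other feature (Spearman rank
correlation, Bonferroni-combined per feature) to support an MCAR-vs-MAR
judgement. The test backing the published per-feature p-values is unnamed
in the source; this diagnostic is a documented choice, not a reproduction.

## State and action discretization

Features are z-scored on the training split only; validation and test rows
reuse the frozen scaler, preventing leakage. k-means (multiple restarts,
fixed seed) defines the state space; `select_k()` scores candidate `k`s by
BIC and AIC under a spherical-Gaussian likelihood but is off by default --
the published model fixes `k = 650`, and fixing `k` mirrors the model while
selection mirrors the method. State membership of new rows is the
Euclidean-nearest centroid, ties to the lowest index.

Ideal body weight is `50 + 0.91 (height - 152.4)` kg for males and
`45.5 + 0.91 (height - 152.4)` for females. Printed bin edges touch
(e.g. "5-7" / "7-9"); bins are half-open from the lower edge, so a boundary
value belongs to the upper bin. FiO2 below the first printed edge is folded
into the first bin, since inspired oxygen below room air is non-physical.
Extra action dimensions (e.g. respiratory rate) can be appended with
user-supplied edges; the flat index simply multiplies.

## Solving and evaluating policies

`solve_optimal_policy()` defaults to model-based value iteration on
`(T, R, gamma)` to a Bellman residual below 1e-8; a sample-based tabular
Q-learning mode (replay over the observed transitions, visit-count
learning-rate schedule) converges to the same fixed point of the empirical
MDP and is kept for fidelity to the method's usual name. Greedy ties break
to the lowest flat action index. Actions observed fewer than `min_count`
(default 5) times in a state are masked as ineligible so the policy cannot
recommend essentially unobserved settings; a *visited* state whose actions
are all masked raises an error, while states never visited in training get
value 0 and a flagged uniform policy.

Off-policy evaluation is by weighted importance sampling (WIS) against the
empirical behavior policy `N(s, a) / N(s)`. The deterministic greedy policy
is softened (epsilon-greedy over eligible actions, default epsilon 0.05)
before weighting, because a deterministic target makes the weights
degenerate. Two estimators ship: plain per-trajectory WIS, and the default
"stepwise" consistent weighted per-decision estimator (per-step
self-normalized cumulative weights). The latter is the package's documented
stand-in for an unspecified multiplicative control variate and is labelled
as such in every result object. Percentile bootstrap over whole
trajectories (default B = 1000) yields one-sided confidence bounds: the
level-L lower bound is the `(1 - L)` quantile. The central 90% interval
therefore runs from the 95% lower bound to the 95% upper bound.

`run_ensemble()` repeats the whole cycle (default 500 models): a fresh
random 60/20/20 train/validation/test split of stays per model -- the
reconciliation of the two split descriptions in the source (60/20/20 study
design; 80/20 with bootstrap-on-validation learning scheme): clustering and
MDP estimation on train, bootstrap-WIS selection on validation, final
reporting on the selected model's test partition. The selected model
maximizes the 95% lower bound of the AI policy; clinician (behavior) and
random policies are evaluated alongside. The behavior policy used for
weighting is estimated from the train+validation transitions, never from
test.

TD(0) evaluation of the clinician (`evaluate_clinician_td()`) and linear
policy evaluation on the estimated MDP are both exposed; which of the two
the published "best performance" versus "observable behavior" figures
correspond to is not stated, so neither is claimed as the exact published
estimator.

## The synthetic cohort generator

`generate_ground_truth()` and `simulate_cohort()` exist so that every
pipeline stage has an oracle: the true kernel, the true optimal and
behavior values (computed by linear solve at construction), the true state
labels and controlled missingness. The generator's statistical contract is
that its ground truth is *recoverable* at realistic cohort sizes:

* A scalar **severity** per state drives the per-step absorption
  probability (`0.08 + 0.17 * severity`), the death odds given absorption,
  and the emission mean of the first feature, so features are informative
  of prognosis.
* Each state has one designated beneficial regime (quality 1; other
  actions draw quality from `U(0, 0.5)`). Quality lowers the death odds
  (logit `2.5 (severity - 0.5) + 2 - 4 quality`) and tilts the
  Dirichlet(0.5) next-state draw toward lower-severity states
  (`drift = 2`): treatment affects disease progression, not only terminal
  mortality. Without this, the optimal action's advantage lives entirely
  in rare +/-100 terminal events and is statistically invisible at
  5,000 stays -- the recovery guarantees would be unattainable for any
  estimator.
* Emission means are drawn with a between-state SD of 5 against
  within-state noise SD 1, satisfying the separation (scatter ratio >= 5)
  under which cluster recovery is claimed.
* The behavior policy is a softmax over per-state *standardized* action
  preferences at temperature tau = 2 (plus N(0, 0.25) perturbation). On
  raw Q values, which span +/-100, any fixed temperature is either
  effectively greedy (destroying the behavior-policy overlap that
  importance sampling needs) or uniform; standardization restores the
  intended "mostly sensible, sometimes suboptimal" clinician. `tau = 0`
  recovers the exact greedy policy.
* Stays unresolved after the 18-bin window are continued, unrecorded,
  until absorption to obtain the outcome -- mirroring mortality
  ascertained after the 72-h observation window. Default injected
  missingness is 10% MCAR per feature cell with 1% gross outliers
  (cells scaled by 8); a MAR mechanism driven by the first feature is
  available.

What the generator does **not** emulate: pharmacology, charting artifacts,
informative observation times, inter-feature correlation beyond the shared
severity axis, and non-Markovian dynamics. Passing the recovery suite
therefore shows that the pipeline is a correct implementation of the
estimators on data satisfying its assumptions -- not that those
assumptions hold in any real ICU.

## Problem sizes and numerical choices used in validation

The validation suite runs at sizes chosen to make each check sharp:

* Solver identities on toy MDPs (2-4 physiologic states, 2 actions) with
  probabilities in exact tenths, against an exhaustive
  policy-enumeration oracle evaluated by linear solve (tolerance 1e-6;
  1e-3 for the stochastic Q-learning fixed point). The 1e-6 Q-learning
  check uses deterministic dynamics with a unit learning rate, where the
  sampled target equals the expected target and the update is exact.
* WIS calibration on a 4-state toy: a single 5,000-trajectory run within
  two Monte-Carlo standard errors of the closed-form value, and 200
  replications of 500 trajectories (B = 200) in which the central 90%
  bootstrap interval covers the truth in at least 80%.
* End-to-end recovery: 20 latent states, a reduced 2x2x2 action grid
  (8 actions), 5,000 stays, a 24-feature fingerprint (resolves the states
  as well as the full 44 at half the simulation cost), k-means with 10
  restarts. Checked: clustering ARI >= 0.8 against the hidden labels;
  greedy-policy agreement with the true optimal action on >= 90% of
  visited states; and the ensemble-selected policy's *true* value
  dominating the behavior policy's true value.
* The transition estimator is checked against the exact multinomial
  sampling bound (`0.5 * sum_j sqrt(p_j (1 - p_j) / N)` per pair) rather
  than a fixed total-variation constant: at N of a few hundred
  observations per (state, action) pair, no estimator can pin a
  22-outcome distribution to a small constant.

Degenerate inputs are handled explicitly: all-missing features warn and
pass through the outlier filter untouched; constant series flag a zero
state-time correlation; a constant regression target yields zero feature
importances with a warning; empty return bins are marked, never
interpolated; fewer than two trajectories make bootstrap bounds degenerate
with a warning; and `gamma = 1` with a non-absorbing recurrent class is a
named error in exact policy evaluation.

## Known limitations

* WIS is consistent but biased toward the behavior value in small samples,
  and its percentile bootstrap undercovers when the effective sample size
  collapses (heavily softened targets against concentrated behavior).
  The effective sample size is reported in every `ope_result` for exactly
  this reason.
* State aggregation confounds action values when clusters mix latent
  states whose behavior policies differ -- observed directly in
  development as inflated Q estimates for rarely-taken actions inside
  impure clusters. Granular state spaces (the published 650) and the
  eligibility mask mitigate but do not remove this.
* The random-forest importance analysis is descriptive: out-of-bag
  permutation importances are floored at zero and normalized, and a
  bagged forest is only stochastically invariant to feature order.
* Tabular methods only: no function approximation, no continuous actions,
  no fitted-Q evaluation.
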