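---
title: "Models and methods in twostepgaze"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in twostepgaze}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the scientific and numerical choices behind the
package: the task generator, the hybrid learning model, the estimator, the
behavioural and gaze statistics, and — since no human data ships with the
package — what the synthetic-data generator does and does not emulate.

## The task generator

A session is 150 trials of the two-stage Markov decision task. The design
constants live in `task_config()`:

* `n_trials = 150` — one session per condition.
* Per-trial common-transition probabilities, one per first-stage symbol,
  are drawn independently every trial from Uniform(0.4, 1); the long-run
  mean is 0.7. The same sampler runs in both conditions — in the cued
  condition the per-trial value is displayed to the subject, in the
  uncued condition it is generated but not shown (a `condition` flag
  records which). The uncued condition is therefore *not* a fixed-0.7
  design; the marginal common-transition frequency is still 0.7.
* The four second-stage reward probabilities drift as Gaussian walks
  (mean 0, sd 0.025 per trial) in [0.25, 0.75]. Boundary handling is not
  prescribed by the design, so a choice was needed: steps are **reflected**
  at the bounds. Reflection preserves the stated marginal range without
  the sticky-boundary artefact of truncation (a truncated walk piles
  probability mass at 0.25/0.75). Initial values are drawn uniformly from
  the same range, again a choice the design leaves open.
* Rewards are binary; the monetary conversion of reward points is
  bookkeeping outside the model and is not represented.

The colour cue of the second condition is the signed deviation of a
symbol's common-transition probability from its mean:
`colour_deviation(p, 0.7) = p − 0.7`, in [−0.3, +0.3]. A deviation of
−0.3 corresponds to a bar entirely of the rare state's colour, 0 to a
half/half bar.

## The hybrid learner

All value updates follow the standard delta-rule family, with zero
initialization and the update order: stage-1 model-free update, stage-2
update (both using the *pre-update* second-stage value), then the
transition-count increment. The free parameters, their ranges and their
roles:

| parameter | range | role |
|---|---|---|
| `alpha` | [0, 1] | learning rate of both delta rules |
| `beta` | ≥ 0 | inverse temperature of both softmax stages |
| `lambda` | [0, 1] | eligibility trace: weight of the reward prediction error in the first-stage update |
| `p_stick` | real (fit clamps to ±10) | logit-units bonus for repeating the previous first-stage choice |
| `w` | [0, 1] | model-based weight |
| `v` | [0, 1], `w + v ≤ 1` | colour-cue weight (condition 2) |

Three places needed a decision where the published description is loose:

* **Stickiness scaling.** The stickiness bonus enters the choice logit
  *unscaled* by `beta` (`P(a) ∝ exp(β Q(a) + p·1(a = prev))`), so fitted
  `p` values are interpretable in logit units independently of `β`. The
  bonus is zero on trial 1, where there is no previous choice.
* **The condition-2 cue correction.** The cue weight is described only as
  a weight "assigned to the correction"; the implemented form is the
  additive correction `v · Δp(a) · [max Q2(common(a)) − max Q2(other(a))]`.
  This form has the property that setting `v = w` reproduces exactly the
  fully informed model-based value evaluated at probability
  (posterior mean + Δp) — i.e., equal weighting of cue and learned base
  probability is the optimal-use benchmark, which is what makes the
  fitted `v` vs `w` comparison meaningful. The identity is asserted in
  the test suite, symbolically derived and numerically checked.
* **State carry-over between conditions.** Q-values are re-initialized at
  the start of condition 2 (reward probabilities are reset in the task),
  but transition counts and the previous-choice memory persist (the
  symbols keep their transition structure). Fitting is nevertheless done
  per condition with a fresh state, mirroring the separate analyses; the
  first few trials of a condition then carry slightly misspecified
  transition priors, which is common to any per-condition analysis of
  this design.

## Maximum-likelihood fitting

`negative_log_likelihood()` replays the observed history and sums
`−log P(a1) − log P(a2)` over trials; the hot loop is compiled (Rcpp)
because the multistart estimator evaluates it hundreds of thousands of
times. An independent, deliberately naive R replay oracle lives in the
test suite and must agree to 1e-10.

`fit_subject()` runs Nelder-Mead from `n_starts` random starting points
drawn uniformly in the *unconstrained* space: bounds are enforced by
smooth reparameterization (logit for `alpha`, `lambda`, `w`; log for
`beta`, with starts spanning β from 0.5 to 20; clamped identity for
`p_stick`; a stick-breaking map `w = σ(z1)`, `v = (1 − w) σ(z2)` for the
condition-2 simplex). Numerical choices:

* Default `n_starts = 50`, scaled down from the reference 10,000 for
  runtime; the parameter-recovery acceptance test shows 50 starts suffice
  at 300 trials. Starts are drawn one at a time so the first *m* starts
  of an *n*-start fit coincide with an *m*-start fit — multistart
  monotonicity holds by construction and refits with the same seed are
  bit-identical.
* `p_stick` is clamped to ±10 logit units inside the objective: perfectly
  sticky synthetic histories otherwise drive it to infinity.
* BIC uses `n_obs = 2T` because both stage choices contribute likelihood
  terms; the published description does not say which convention it uses,
  so this one is stated explicitly.
* Convergence uses `optim`'s relative tolerance (1e-8); a fit where no
  start converges returns a flagged result rather than an error.

`classify_subjects()` median-splits fitted `w`: below the sample median is
model-free, at or above it model-based; an all-equal vector degenerates to
all-model-based with a warning.

## Behavioural statistics

`build_stay_design()` produces, per trial t ≥ 2, the stay indicator and
the previous trial's reward and transition type (common = 1). The
condition-2 colour regressor is the current trial's colour deviation for
the common state of the previously chosen symbol minus the deviation for
that same state for the other symbol; because the two symbols' common
states are complementary this equals the sum of the two symbols' own
deviations.

Hierarchical (mixed-effects) logistic regression is deliberately replaced
by a two-level surrogate: per-subject ML logistic fits, then a one-sample
t-test of each coefficient across subjects. This preserves the
inferential pattern (all coefficients subject-level random effects)
without the hierarchical machinery, which is out of scope here. Subjects
whose fit separates (fitted probabilities pinned at 0/1 or |coef| > 15)
are flagged and excluded from the group test with a warning. Dwell-time
predictors in the choice/gaze regression are standardized within subject
before fitting; the raw-seconds alternative is a one-line change but the
standardized form is what the package reports.

## The gaze pipeline

ROIs are the symbol boxes (400 × 290 px) plus a 50 px margin, vertically
centred at 33% of screen height, and same-sized bar ROIs at 80% height.
The stated "horizontal distance between ROIs of 460 px" is ambiguous
(edge-to-edge of the boxes vs of the ROIs); the implemented default reads
it as **460 px between the symbol-box inner edges**, with the margins
extending 50 px into that gap from each side (inner ROI edges 360 px
apart, so the two ROIs can never both contain one sample). The whole
geometry is configurable through `screen_geometry()` if a user prefers
the other reading.

Samples → events is run-length encoding of ROI labels; event offsets
extend one sampling interval past the last sample so that k samples at
1000 Hz make a k ms dwell. Cleaning merges same-ROI events separated by a
gap (blink/tracker dropout) into one gaze and leaves cross-ROI gaps as
plain gaps; merged dwell **excludes** the gap time by default (a blink
adds no evidence), with a `gap_inclusive` flag for the span-inclusive
alternative — the original analysis does not say which it used, so both
exist and the default is recorded here. Cleaning is idempotent and never
increases event counts or total dwell; both properties are fuzz-tested.
Trials with no on-ROI gaze are excluded and counted per subject.
Event-level input bypasses ROI assignment entirely, so pre-parsed
eye-tracker exports can enter at `clean_events()`. No minimum-duration
threshold is applied by default.

## The synthetic-data generator, and what a green test means

`generate_study()` produces subjects whose learning parameters come from
documented priors — `alpha, lambda, w ~ U(0, 1)`, `beta ~ LogNormal(log 5,
0.5)` (centring β on values typical of fits in this task family),
`p_stick ~ N(0, 1)`, condition-2 `(w, v)` uniform on the simplex — and
whose gaze streams come from one of two *descriptive* processes:

* **comparison** (assigned when `w < 0.5`): first gaze side uniform and
  independent of values; mostly ≥ 2 strictly alternating gazes
  (single-gaze probability 0.32); middle dwells log-normal around 500 ms,
  shrinking with |ΔQ| (easier choices end sooner); the chosen symbol's
  dwells inflated by 1.35 and the last gaze on the chosen symbol with
  probability 0.78 — producing the last-gaze and dwell-advantage choice
  effects.
* **search**: the first gaze lands on the to-be-chosen symbol with
  probability `σ(0.3 + 2.5 |ΔQ|)`; if it found that symbol the trial
  usually ends after a single gaze (stop probability 0.75), otherwise a
  short confirmation sequence ends on the chosen symbol; dwell-advantage
  coupling is weak (boost 1.05).

Because gaze is generated *conditional on* the already-made choice, the
alternation constraint couples first gaze, last gaze and gaze count; the
gaze-count draw absorbs the parity constraint (±1 gaze), which slightly
reshapes the nominal count distribution — the realized single-gaze rates,
not the nominal parameters, are what the tests assert (search > comparison,
and distinguishable count distributions). Bar attention in condition 2 is
generated with target share `0.5 + 0.2 w + 0.15 v`, an increasing function
of the ground-truth weights chosen to span roughly the 0.55–0.85 range and
to make the bar-share-vs-w correlation testable in direction. No-gaze
trials occur at rate 20/150.

These generators are pattern emulators, not a fitted sequential-sampling
model: they reproduce the qualitative regularities the analyses test for
(value-independence of the comparison first gaze, value-dependence of the
search first gaze, dwell/choice coupling, single-gaze rates, bar-share
coupling) with hand-set magnitudes. A green test therefore establishes
that the *pipeline* detects structure that is present and stays silent
when it is absent — it does not establish that real subjects have these
effect sizes, and none of the published subject-dependent numbers (median
weights, bar-share percentages, regression tables, correlations) are
reproduction targets. Response times, pupil data, calibration drift and
saccade kinematics are not modelled at all; rasterized samples are ROI
centres with Gaussian jitter, which makes ROI assignment nearly
noise-free compared to real data.

## Known limitations

* The per-subject + t-test surrogate is less efficient than a true
  hierarchical fit for small, unbalanced designs and cannot estimate
  between-subject interaction terms within one model; the pooled
  `fit_choice_regression()` GLM is a fixed-effects approximation.
* Per-condition fitting ignores the transition-count carry-over that the
  study-level generator implements (see above).
* With ~150 trials, `w` estimates for low-`beta`, low-`alpha` subjects
  are weakly identified; the recovery acceptance test quantifies this at
  300 trials, and the fit degrades gracefully (finite estimates, flagged
  convergence) rather than failing.
* The two-rate/two-temperature model variant exists for BIC comparison
  but is not the default anywhere, matching the design's preference for
  the 5-parameter model.
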