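---
title: "The PVT vulnerability pipeline: model, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The PVT vulnerability pipeline: model, assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, eval = FALSE}
library(pvtvuln)
```

This vignette documents the modelling decisions behind `pvtvuln`: the
generative model of the synthetic cohort, how its defaults were calibrated,
the exact numerical conventions used by the analysis stages, and what the
package deliberately does not claim. Code chunks are illustrative and not
evaluated when the package is built; the quantitative statements below are
the ones enforced by the package's test suite and acceptance script.

## 1. The task and the protocol

The Psychomotor Vigilance Test (PVT) is a 10-minute simple reaction-time
task: a stimulus appears after a uniformly random 1–9 s inter-stimulus
interval and the participant responds as quickly as possible. Reaction times
(RTs) above 500 ms are *lapses* of attention; RTs below 100 ms are
anticipatory *false starts*. The simulated protocol is a constant routine:
PVT sessions every 2 h while awake, with baseline sessions at 4–14 h after
wake on days 2–4 and, on day 4, continued testing into total sleep
deprivation (TSD) at 16, 18, 20, 22 and 24 h after wake.

`pvt_protocol()` encodes the schedule, session duration, ISI range, error
rates and the trait-distribution parameters; `write_protocol()` /
`read_protocol()` serialize it as JSON (or YAML when the yaml package is
available) so runs are fully configuration-driven.

## 2. The generative model

Each participant carries seven traits, constant across sessions
(`sample_cohort()`):

* `base_speed`, `base_sd` — mean and dispersion of log attentive RT;
* `lapse_propensity` — baseline log-odds that a trial is a lapse-state trial;
* `homeo_gain` — growth of those log-odds per hour awake beyond 16 h
  (initial slope);
* `circ_amp`, `circ_phase` — circadian modulation of the lapse odds;
* `tot_gain` — within-session time-on-task growth of the lapse odds.

The first four are linear images of a 4-dimensional standard normal with
within-block correlations (`speed_sd_cor = 0.3`,
`propensity_gain_cor = 0.2`) and a cross-block correlation
(`trait_correlation = 0.4`) between the speed block and the vulnerability
block. That cross-block correlation is what makes baseline performance
partially predictive of TSD vulnerability — the scientific premise under
test.

A session is a renewal process: trial *i* starts one ISI after the response
to trial *i − 1* and trials stop at the scheduled duration. Each trial is,
with small fixed probabilities, a false start (RT uniform on 10–90 ms) or a
wrong-button press; otherwise it is drawn from a two-component mixture:

* **attentive state**: lognormal RT,
  `log RT ~ N(base_speed + 0.005·minute, base_sd²)`;
* **lapse state**: shifted-Pareto RT, `RT = 500·U^(−1/2)` ms (tail index 2),
  capped at 30 s; a capped trial is recorded as a timeout with missing RT.

The per-trial lapse-state log-odds are

```
eta(t, m) = lapse_propensity
          + homeo_gain · b(t)
          + circ_amp · cos(2π (t − circ_phase) / 24)
          + tot_gain · m
```

with `t` hours since wake and `m` the within-session minute of the stimulus
onset. The homeostatic basis is saturating rather than linear:

```
b(t) = τ (1 − exp(−max(0, t − 16) / τ)),   τ = 3 h
```

so `homeo_gain` keeps an interpretable per-hour meaning as the initial slope
at 16 h awake, while the predicted lapse counts level off across the late
TSD sessions instead of exploding by 24 h. A purely linear ramp cannot keep
all five TSD sessions' lapse counts inside realistic group bands at once;
saturation of sleep-pressure effects over a day-scale constant routine is
also the physiologically defensible shape. Monotonicity — more hours awake
and larger `homeo_gain` both increase expected lapses — is preserved and
tested.

### Calibration of the defaults

The trait-distribution defaults in `pvt_protocol()` were fixed once, by
simulation from candidate parameter sets before the test suite existed, so
that a default 160-participant cohort reproduces the study conditions the
analysis assumes:

* group mean TSD lapse counts inside the conventional
  resilient (0–13.6), intermediate (14.0–30.4) and vulnerable (30.6–52.8)
  bands;
* baseline lapse rates explaining roughly half of the between-participant
  variance in TSD lapse rates;
* roughly 37 % of participants averaging ≤ 2 lapses per baseline session
  (the "high-performer" subgroup);
* a strong rank correlation between the generative `homeo_gain` and the TSD
  outcome, so the labels are recoverable in principle.

These properties are asserted (with tolerances reflecting sampling noise) in
the test suite. The frozen values live in the `pvt_protocol()` defaults, and
`example_traits()` exposes quartile-centre trait profiles (|z| = 1.27, the
mean of a standard-normal quartile tail) whose simulated TSD lapse means
fall inside the vulnerable and resilient bands.

The generator's scope is deliberately limited: traits are stationary (no
day-to-day state noise beyond the session-level randomness), circadian phase
does not interact with the homeostat, sleep inertia and recovery sleep are
out of scope, and invalid sessions are injected only through the four
explicit corruption modes used by the QC stage.

## 3. Session quality control

`validate_session()` flags a session as invalid when any of the following
holds: administered more than 1 h after schedule (strict), wrong-button
responses on more than 10 % of recorded trials (strict), any interval longer
than 60 s without a recorded response — measured between consecutive
response completions and from session start to first response and last
response to session end, with timeouts not counting as responses — or a
duration under 8 min. An empty session is *missing*. `select_participants()`
excludes a participant only when a TSD session is missing or invalid,
because those five sessions define the outcome; an invalid baseline session
merely contributes no feature vector at that time point.

## 4. Feature catalog

`pvt_catalog()` enumerates 215 per-session measures in nine families. All
RT-distribution features exclude false starts (RT < 100 ms), wrong-button
trials and timeouts; timeouts still count as lapses and both error types are
counted by the error family. Numerical conventions, stated because dialects
differ:

* percentiles use the type-7 (linear interpolation) empirical quantile;
* lapse and consecutive-difference counts use strict inequalities;
* time-on-task slopes are OLS slopes against the stimulus-onset minute, and
  are `NA` when the responded trials span ≤ 1 min;
* features undefined on a session (fewer than 2 RTs, empty sessions) are
  `NA`, never imputed.

Every feature is checked against an independently coded oracle
(`stats::quantile`, `lm()`, explicit loops) in the acceptance tests.

## 5. Outcome stratification

The outcome score is the mean 500-ms lapse count over the five TSD sessions.
`assign_labels()` ranks participants and labels the lowest `floor(n/4)`
resilient and the highest `floor(n/4)` vulnerable (40/80/40 at n = 160,
15/30/15 at n = 60), breaking ties by stable input order. The
high-performer analysis (`select_high_performers()`, boundary-inclusive at
≤ 2 mean baseline lapses) re-stratifies within the subgroup.

## 6. ICC screening

For one feature at one baseline time point, measurements across days 2–4 are
decomposed by `lme4::lmer(value ~ day + (1 | participant), REML = TRUE)`:
the day fixed effect absorbs systematic order effects, the participant
random intercept carries the trait-like signal. The ICC is
`σ²_between / (σ²_between + σ²_within)` with variances truncated at zero and
the degenerate all-zero case defined as 0. Features with ICC strictly above
0.60 survive. On balanced data without the day effect the REML estimates
coincide with the closed-form one-way ANOVA estimators, which the tests
verify; lme4 is used rather than a bespoke REML implementation precisely so
the estimator is a known quantity.

## 7. Cost-sensitive three-class LDA

`lda3()` z-scores features with training-set means and SDs, then fits
linear discriminants with the pooled within-class covariance `S` (divisor
`n − 3`): `w_k = S⁻¹ m_k`, `c_k = −½ m_k' S⁻¹ m_k + log π_k`. The softmax of
the three discriminants is the posterior — algebraically identical to the
Gaussian Bayes posterior under a shared covariance, a property the tests
check against an explicit density computation. Decisions minimize expected
cost `(posterior · C)_k` with `C[true, predicted]` from a one-parameter
family: misclassified extremes cost `c ∈ {1, 1.5, …, 5}`, misclassified
intermediates cost 1. With `c = 1` the rule reduces to the posterior argmax.
Exact ties resolve to the least vulnerable class, deterministically. A
singular pooled covariance falls back along a shrinkage ladder
(0, 0.1, 0.5, 1) toward its diagonal — silently inside cross-validation,
with a warning from the public fitting interface — and a feature with zero
within-class variance is given unit variance so it cannot poison the solve.
Models serialize to JSON and round-trip to identical predictions.

## 8. Wrapper search and cross-validation

`best_first_search()` runs forward best-first selection over feature subsets
jointly with the cost scalar: the highest-scoring unexpanded subset is
expanded by each unused candidate, each child is scored at every cost in the
grid by `evaluate_subset()`, and the search stops after five consecutive
expansions without strict improvement (or at explicit expansion/beam caps).
Scores are mean three-class accuracy over repeated stratified 5-fold
cross-validation: fold assignment shuffles within class and deals
round-robin, so the 1:2:1 ratio is exact in every fold (8/16/8 at n = 160);
z-scoring parameters and discriminants are estimated on training folds only.
Each repeat derives its seed deterministically from the configuration seed,
making every result a pure function of (data, configuration, seed).
`fit_final()` refits the winning subset and cost on all complete cases.

## 9. Evaluation

`cv_metrics()` recomputes accuracy, Cohen's kappa and one-vs-rest
sensitivity/specificity/PPV/NPV (resilient-vs-rest, vulnerable-vs-rest)
within each CV run and reports mean ± SD across runs; rates with zero
denominators are `NA` with a warning, never silently 0. The chance level for
label-independent prediction is `Σ (n_k/n)² = 0.375` for the 1:2:1 split.
`modal_assignment()` gives each participant the most frequent prediction
across runs (ties to the less vulnerable class) and
`group_time_course()` compares the assigned groups' mean lapse counts at
every scheduled session, which is how the package expresses "the predicted
vulnerable group really does lapse more under sleep loss".

## 10. Running the pipeline

```{r pipeline, eval = FALSE}
run <- run_pipeline(pvt_protocol(seed = 1), n = 160,
                    catalog = pvt_catalog(percentile_grid = seq(10, 90, 10)),
                    max_candidates = 10, cost_grid = c(1, 2, 3),
                    cv = cv_config(folds = 5, repeats = 10, seed = 1),
                    max_expansions = 12, out_dir = "artifacts")
metrics_table(run)
```

The reduced settings above (coarser percentile grid, ICC-ranked candidate
cap, 3-point cost grid, 10 CV repeats, expansion cap) keep a full
6-time-point run near a minute; the defaults (215 features, 9-point cost
grid, 100 repeats, uncapped search) trade hours of compute for a closer
match to an exhaustive analysis. `scripts/acceptance.R` wraps the reduced
configuration and writes the headline quantities as JSON.

## 11. Limitations

The cohort is synthetic: results quantify the *internal* consistency of the
pipeline — that the machinery recovers planted, recoverable structure under
its own assumptions — not the empirical predictability of human
vulnerability. The generative model encodes one defensible parameterization
of lapse dynamics; real PVT data have additional structure (motivation,
practice, posture, device timing) that it does not attempt. Classification
metrics obtained here therefore bound what the method can do when its
assumptions hold, and transfer to real cohorts must be established on real
data ingested through `read_trials_csv()`.
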