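---
title: "Methods: engagement-anchored analysis of wearable activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: engagement-anchored analysis of wearable activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(modact)
```

## The question and the data model

Digital behavior-change interventions deliver their content in web modules;
whether visiting a module changes what participants actually *do* can be
asked without any extra instrumentation by anchoring wearable-tracker data
to the module-visit times recovered from server log files. `modact`
implements that analysis for physical-activity modules: goal setting and
action planning ("goal", estimated completion time 10 minutes) and barrier
identification and coping planning ("barriers", 8 minutes).

Three tables drive everything:

* **log events** — `(participant, module, timestamp, enter/leave)`;
* **daily activity summaries** — per participant-day: steps, activity energy
  expenditure (kcal), fairly active, very active and total active minutes,
  and distance (km), as exported by the tracker platform;
* **roster** — participant, trial arm, date of first login.

## Visit reconstruction and the completion rule

A *module visit* is an `enter` event matched to the next `leave` for the
same participant and module with no intervening `enter`. Matching is
strictly per participant–module: entering module B never closes an open
visit of module A, because each module's dwell time comes from that module's
own events. An `enter` never followed by a matching `leave` is a visit whose
duration cannot be determined (a missing end event); a `leave` without an
open `enter` is discarded and counted. Events with equal timestamps order
`enter` before `leave`, so an enter/leave pair at the same second is a
zero-length visit — kept, and classified incomplete, since it is evidence of
a page bounce.

A visit is **complete** when its duration reaches at least 33% of the
module's estimated duration — 3.3 of 10 minutes for goal, 2.6 of 8 for
barriers — *or* when its duration is indeterminable because the end event is
missing. The threshold fraction is a parameter
(`module_spec(completion_fraction=)`); the comparison is inclusive ("at
least") and is made on the unrounded product `fraction × minutes × 60`
seconds with a `1e-9` s tolerance, because in binary floating point
`0.33 × 600` lands a hair above the mathematically exact 198 s.

Two behaviours are deliberately *not* inferred from any source and are
simply declared: rapid revisits (e.g. a reload seconds later) are separate
visits, and a visit's calendar date is the date of its `enter` event in the
dataset's single declared timezone.

## Wear-day validity and event-anchored windows

Trackers record a row even on days the device was barely worn. A day is a
**valid wear day** when `steps >= 1000`; days below the threshold — and
absent dates — are missing data for *all* metrics. Both the threshold and
the windowing minimum below are config fields with these defaults.

Windows are anchored on the visit date:

* **before** = days −7..−1, **after** = days +1..+7 — the visit day belongs
  to neither, because behaviour on it is contaminated by partial exposure;
* **week k** = days `7(k−1)+1 .. 7k`, k = 1..8, so week 1 *is* the after
  window and the nine windows tile 63 distinct offsets.

A window's metric means are defined only when it contains at least 4 valid
days (`min_valid_days`); a before/after *pair* exists only when both windows
are defined. Each visit anchors its own pair — a participant with three
visits contributes three paired observations — and overlapping windows of
nearby visits are not deduplicated; the per-participant sensitivity analysis
(below) is the guard against both choices.

## Tests and tables

Activity metrics are skewed, so all summaries are medians with
interquartile ranges (quantile type 7, linear interpolation — the
convention is a parameter because software families disagree) and all
comparisons are two-sided **Wilcoxon signed-rank tests** at α = .05, with
no multiple-testing correction; tables carry the number of tests so readers
can apply their own.

The signed-rank implementation drops zero differences (the classic rule,
not the Pratt variant), ranks absolute differences with average ranks for
ties, and takes `W` = sum of positive-difference ranks. For
`n_effective ≤ 25` the two-sided p-value is exact: the null distribution of
`W` is built by shift-convolution over the doubled ranks (doubling makes
midranks integral), which equals full enumeration of the `2^n` sign
assignments but costs `O(n · Σr)`. Above the cutoff a normal approximation
is used with tie-corrected variance `Σr²/4` (identical to the classical
`n(n+1)(2n+1)/24` minus the tie term) and a continuity correction. Exact
and approximate routes agree within 0.02 for `n_effective ≥ 12` on
near-continuous data; below that the exact distribution's lattice spacing
(two-sided increments of `2/2^n`) makes such a bound unattainable, which is
why the automatic cutoff favours the exact route for every small sample.

Three tables mirror the reporting layout of engagement studies:

* **immediate effects** — per metric, before vs after medians (IQR), `W`,
  p, and a significance tier (`P<.05/.01/.001`), for *all* visits and for
  *complete* visits only;
* **sustained effects** — for complete visits, the three active-minute
  metrics per window (before, weeks 1–8), each week tested against the
  pooled before window (the before row pools every complete visit with a
  defined before window; each week's test uses the visits where both
  windows are defined — the week rule matches the immediate rule, 4 valid
  days, overridable);
* **per-participant sensitivity** — each participant's before- and
  after-values averaged first so everyone contributes one pair.

## The synthetic cohort

No participant-level trial data accompany the analysis, so the package
generates cohorts whose structure matches what the pipeline assumes, with
full ground truth. Defaults (all `cohort_config()` fields):

* 800 eligible participants in two arms; first logins staggered over 60
  days; 250 days of daily data each;
* goal-like module: visit probability 0.614, first-visit delay lognormal
  with median 55 days; barriers-like: 0.501 and median 98 days — delay
  spreads chosen so the quartiles land near 48–64 and 91–110 days;
  extra visits per visitor Poisson(≈0.26) (≈1.26 visits/visitor), mean gap
  21 days;
* timed-visit durations land above the completion threshold with
  probability 0.49 (goal) / 0.67 (barriers) — matching completion
  proportions of roughly 309/628 and 345/514 once the 10% of visits with a
  dropped leave event (complete by the missing-end rule) are added;
* daily steps lognormal with median 9500 (between-person sd 0.30 log units,
  day-to-day 0.25); fairly/very active minutes gamma with population means
  18/26 min (between-person lognormal sd 0.45, day shape 4), which puts the
  marginal medians near 17 and 24 min; distance and energy co-vary with
  steps through per-person stride and kcal-per-step factors;
  `total_active_min = fairly + very` by construction;
* wear probability 0.9; non-wear days draw steps uniformly in [0, 999] so
  the threshold filter is exercised (a flag drops the rows instead, to
  exercise the absent-date path);
* an optional additive effect `effect_delta_min` on very-active (or fairly
  -active) minutes, applied on wear days from day +1 after the
  participant's **most recent** completed visit, decaying linearly to zero
  over `7 × effect_decay_weeks` days (0 = persistent). The ground truth
  stores each day's pre-effect baseline and exact effect contribution, and
  each visit's true duration and completion status, so every pipeline count
  and windowed mean can be recomputed independently (`expected_pairs()` does
  so with plain loops).

One realistic artifact is worth knowing: with repeat visits, a revisit's
before window can sit inside an earlier visit's effect period, and an early
visit's late weekly windows can overlap a later visit's effect. On
cohorts with injected effects this shows up as late-week *decreases*
relative to the (elevated) before window. It is a property of the design,
not a bug — the trial-like analysis has the same exposure overlap — and it
is why the calibration experiments below use a cleaner design.

What the generator does *not* emulate: minute-level or heart-rate data,
device accuracy, seasonal and weekday structure, behavioural
autocorrelation beyond the per-person baselines, or informative non-wear
(wear days are missing completely at random). Passing tests therefore
validate the *pipeline arithmetic* under known structure, not the
substantive findings of any trial.

## Calibration and power experiments

The acceptance tests run three simulation experiments, all on a
single-module, single-visit-per-participant design (`experiment_config()`:
barriers-like module only, revisit rate 0, daily data covering the delay
distribution plus the analysis horizon). One visit per participant keeps
every before window and late weekly window free of the exposure-overlap
artifact above, so the median paired difference estimates the injected
effect directly:

* **type-I error** — 500 null cohorts (effect 0, n = 200 participants,
  ≈60–80 completed pairs each): the very-active rejection rate at α = .05
  must lie in [0.03, 0.07];
* **effect recovery** — 100 cohorts with +10 very-active min (n = 500,
  ≈220 pairs): mean recovered median paired difference within 1 min of 10,
  and the immediate-effect table flags the metric in > 80% of replicates;
* **sustained shape** — 100 cohorts with +10 min decaying to zero by week 4
  (`effect_decay_weeks = 4`: multiplier `1 − (d−1)/28` on post-visit day d):
  weeks 1–3 all flagged and at least 3 of weeks 5–8 not flagged, in ≥ 80%
  of replicates. ("Reverts toward ns" needs a concrete form; *all four*
  late weeks clean would fail ≈19% of the time by chance alone at a true
  5% level, `0.95^4 ≈ 0.81`.)

These sizes keep the full suite within a few minutes on one CPU while
leaving the binomial noise of each rate well inside its acceptance band.

## Degenerate inputs and numerical choices

* All-zero paired differences: `W = 0`, `p = 1`, flagged degenerate.
* Empty metric groups or windows: rows with `NA` statistics, never silent
  omission; an empty daily table completes the run with a warning.
* Malformed log rows (unknown event type, bad timestamp, missing id) abort
  the read with a row-numbered report; duplicate participant-days and
  negative durations are hard errors.
* Visits dated before first login are excluded from delay summaries with a
  warning, as data errors.
* The filter funnel is asserted on every run on the participant scale
  (participants with tested pairs ≤ participants with windowed visits ≤
  visitors ≤ eligible) plus pair-scale subset checks; the visit scale is
  not monotone in visitors because participants revisit.

## Worked example

```{r example, eval = FALSE}
library(modact)

cfg <- cohort_config(n_participants = 300, effect_delta_min = 6,
                     effect_decay_weeks = 4, seed = 7)
run <- run_simulate_analyze(cfg)

run$user_stats                           # engagement funnel
run$delays$summary                       # first-visit delays
render_effect_table(run$results$barriers$immediate_completed)
render_effect_table(run$results$barriers$sustained)
run$ground_truth_report                  # recovered vs injected effect
```

The `analysis/` directory holds the same workflow as five numbered scripts
(simulate → engagement → immediate → sustained → sensitivity) writing their
tables under `results/`.

## Known limitations

Engagement is log-file dwell time only — nothing about the quality of the
plans users typed. Rank tests cannot carry a random participant effect, so
repeat visits enter as independent observations, with the per-participant
averaging as the sensitivity check. No imputation is attempted for missing
days, and no correction for the tracker's known overestimation of
moderate-to-vigorous activity is modelled.
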