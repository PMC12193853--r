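---
title: "Methods: personalized hypoglycemia detection from smartwatch data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: personalized hypoglycemia detection from smartwatch data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hypowatch)
```

## The detection problem

A blinded continuous glucose monitor samples interstitial glucose every five
minutes and defines the outcome: a hypoglycemic minute is one inside a
maximal run of glucose strictly below 4 mmol/L lasting at least 15 minutes.
The smartwatch channels — heart rate, heart-rate variability (HRV), step
count, active energy, and (at night) respiratory rate and blood oxygen
saturation — are the only predictors; glucose never enters the feature set.
The scientific question is whether a *personalized* classifier, trained and
tested exclusively on one person's own data, can recognize the
physiological signature of hypoglycemia minute by minute.

Because consecutive minutes of physiology are strongly autocorrelated, a
random row split would leak information between train and test and inflate
performance. A strictly temporal split is also unworkable: events are rare
and may not occur on both sides of any cut. The pipeline therefore splits on
whole *diurnal segments*. Each day (wake to sleep onset) and night (sleep
onset to wake), as declared by the participant's diary, gets a unique
identifier; every segment containing at least one event is held out once as
the test set while all remaining segments of the same kind train the model.
Metrics are averaged over undersampling seeds within an iteration, then over
iterations, so each held-out event segment carries equal weight.

## Preprocessing and its leakage discipline

All channels are merged onto a single 1-minute grid (multiple observations
within a minute are averaged — a cadence-robust choice for device exports
with sub-minute duplicates). Imputation is deliberately asymmetric:

* **Glucose** is *backfilled* up to 5 minutes — one CGM sampling interval —
  because the label generator may look at the future but features never
  read glucose.
* **HRV and respiratory rate** are *forward-filled* up to 15 minutes and
  **blood oxygen saturation** up to 30 minutes, i.e., only within one
  nominal sampling interval, and never from the future. The fill-limit
  boundary is inclusive: a cell exactly 15 minutes after an HRV observation
  is still filled.
* **Heart rate, steps and energy** are never imputed; the tree ensemble
  handles missing values natively via learned default directions.

Every cell carries a provenance flag (`observed`, `backfilled`,
`forward_filled`, `missing`), and the test suite asserts that every imputed
cell's source observation lies within its limit and on the correct side of
time. Both imputations are idempotent and never alter observed cells.

Missing glucose breaks a label run. This is the conservative reading: a gap
longer than the backfill limit means we genuinely do not know the glucose
level, and fabricating an event across it would create labels unsupported by
data. A consequence worth knowing: borderline 15–19-minute episodes
adjacent to a sensor gap can fail to qualify.

Prolonged nocturnal events are truncated at 180 labeled minutes (the event
is kept, its labels beyond minute 180 are reset), so a single long overnight
episode cannot dominate a night segment's positive class. The rule is
nocturnal-only; day events are never truncated.

## Feature engineering

Fifteen variables are derived, all causal — the value at minute *t* is a
function of data at minutes ≤ *t* only, which the tests verify by perturbing
future raw samples and asserting bitwise-identical features at *t*:

| Feature | Definition |
|---|---|
| `hr_ra10/30/60` | trailing mean of HR over 10/30/60 min, non-missing values only |
| `hrv_last` | forward-filled last HRV value (15-min limit) |
| `hrv_delta` | difference between the two most recent HRV observations, held until the next observation; missing before the second observation |
| `steps_rs30/60`, `energy_rs30/60` | trailing sums over 30/60 min; missing minutes add 0 (count semantics) |
| `bos_last`, `rr_last` | forward-filled nocturnal channels |
| `tod_sin`, `tod_cos` | sin/cos of 2πh/24 with fractional hour h, so 23:59 borders 00:00 |
| `time_since_meal` | floor of hours since the last diary meal, capped at 12 h (bounds the overnight ordinal range); missing before the first meal |
| `insulin_on_board` | stepwise decay of the most recent short-acting dose: 1.0, 0.75, 0.5, 0.25 over the four hours after administration, 0 beyond |

Rolling windows are trailing, not centered — "rolling" without an
orientation would otherwise peek ahead. The time-of-day encoding uses
fractional hours for smoothness (an integer-hour variant would step once per
hour). Insulin doses are diary ticks without dosage, so dose stacking is not
modeled: the most recent dose wins, and hour boundaries are half-open
upward (a value exactly k hours after a dose belongs to hour k).

The waking model uses 13 inputs (cardiac ×5, activity ×4, time ×2,
manual ×2); the sleeping model swaps the four activity features for the two
respiratory channels, giving 11 inputs (cardiac ×5, respiratory ×2, time ×2,
manual ×2). We note that summaries of this design sometimes quote "10"
sleeping features; the category-resolved importance tables that the sleeping
model produces enumerate 11, including the HRV delta, and 13 + 11 is the
only arithmetic consistent with 15 distinct variables and the two-channel
respiratory swap, so this package implements — and its schema tests assert —
the 13/11 pair. Participants with incomplete meal records are modeled
without `time_since_meal` (12/10 inputs).

## Modeling choices

* **Classifier**: gradient-boosted decision trees, binary logistic
  objective, with both L1 (`alpha`) and L2 (`lambda`) regularization set
  to 10 — deliberately strong shrinkage for small personalized training
  sets. Remaining hyperparameters sit at the library defaults (learning
  rate 0.3, depth 6, 100 rounds, single thread) and are recorded in the
  fitted object and the run manifest.
* **Undersampling**: hypoglycemic minutes are a small minority; negatives
  are randomly discarded without replacement down to a 1:1 ratio in the
  training set only, preserving temporal order, repeated over ten random
  states. Undersampling is preferred over synthetic oversampling because it
  neither disrupts temporal structure nor duplicates data. If negatives are
  already the minority, nothing is upsampled.
* **Standardization**: per-feature z-scores with mean/SD estimated on the
  training rows only and applied to the test rows — the leakage-safe
  reading of "standardize before training". A constant feature is centered,
  not divided. (Tree ensembles are scale-invariant, so this mainly
  disciplines the workflow.)
* **Operating point**: the Youden threshold (maximizing
  sensitivity + specificity − 1) is found by exhaustive search over the
  distinct test scores, ties broken toward the higher threshold. It is
  computed on each iteration's *test* scores, mirroring per-iteration
  reporting; this is optimistic relative to a training-derived threshold
  and is documented as such.
* **Degenerate inputs**: a held-out segment whose minutes are all one class
  leaves AUROC undefined; the iteration is flagged invalid and excluded
  from averages. An iteration whose training segments contain no positive
  minutes (the participant's only event segment is the one held out) is
  likewise recorded invalid rather than fitted; a participant-kind with no
  valid iteration contributes no model.
* **Night-schedule screen**: night models are skipped when the SD of
  sleep-onset hour exceeds 3 h (onsets unwrapped around midnight) or any
  night is shorter than 3 h — a stand-in heuristic for excluding shift-work
  and sleep-restriction schedules, which is narratively motivated rather
  than derived from a published rule.

## Interpretability

Per-row Shapley attributions come from the booster's exact tree-path
algorithm; local accuracy (bias + contributions = margin) holds to floating
point and is asserted in the tests. For each model, mean absolute
attributions over all evaluation rows (each iteration's test rows, averaged
over iterations and seeds) are normalized to percentages summing to 100;
category importance is the sum of its member features' shares. Cohort-level
importance averages *percentages* across models — attribution magnitudes are
not comparable across differently scaled models — and renormalizes.

## What the synthetic cohort does and does not emulate

The generator reproduces the *data environment* the pipeline assumes:
channel cadences, night-only respiratory channels, daytime HRV sparsity
(Bernoulli thinning of a 15-minute grid, keep probability 0.5), diary
structure, and ground-truth events recoverable by the labeler to within one
CGM sample. Glucose follows a mean-reverting Gaussian walk around
7.0 mmol/L (a euglycemic baseline) forced below 4.0 for the duration of
each injected event and kept at or above 4.5 outside events, except for
deliberate sub-15-minute dips that exercise the duration filter. Waking
activity is a two-state rest/active Markov chain driving zero-inflated step
and energy bursts, with heart rate coupled to steps; sleep is activity-free.

Default effect sizes — +10 bpm HR, −15 ms HRV, +2 breaths/min RR,
−1.5 percentage-point oxygen saturation during events, applied uniformly
across event minutes with zero lag — are *illustrative*: they encode the
direction and a plausible magnitude of the counter-regulatory response, not
estimates from any real cohort, which reports no such effect sizes.
Consequently, passing the synthetic parameter-recovery tests shows that the
pipeline recovers injected signal under its own assumptions; it does not
certify performance on real wearable data, where responses vary between
individuals, lag the event, and compete with artifacts, sensor drift and
meal-composition effects that the generator deliberately omits.

Default rates (0.6 day events and 0.35 night events per segment, 20–90-min
durations, 3 meals/day, 90% insulin-dose probability, 23:00/07:00 sleep
schedule with 20-min jitter over 10 days) were chosen once to produce
event-rich 10-day records resembling a free-living type 1 diabetes cohort;
they are configuration, not fitted quantities.

## Reproducibility and problem sizes

A single cohort seed fans out deterministically: participant seeds derive
from the cohort seed, and each generator stage (schedule, diary, glucose,
wearables) draws from its own derived stream, so any participant can be
re-simulated in isolation and match the full-cohort run. Undersampling uses
an explicit per-draw seed and restores the caller's RNG state. Identical
configuration and seeds give byte-identical outputs, which the tests assert.

The test suite exercises the full pipeline at sizes chosen for tight
feedback loops: oracle comparisons run on 1,000 random glucose traces and
500 random score vectors; the parameter-recovery study uses two synthetic
cohorts of 4 participants × 10 days (one with cardiac effects injected, one
null) evaluated over the full ten undersampling states, and the importance
study a 2-participant cohort with purely cardiac effects. Scaling
`n_participants`, rates, and `seeds` up is a configuration change only.

## Known limitations

* The Youden threshold on test scores is optimistic; a deployment system
  must pick its threshold from training data.
* Detection metrics count any supra-threshold minute inside an event; they
  do not penalize false alarms at the event level (specificity covers the
  minute level).
* The diary is authoritative for sleep; no sensor-based sleep detection.
* Single fixed timezone per participant; no daylight-saving arithmetic.
* Insulin-on-board ignores dose size and stacking; meal features ignore
  composition.
* Boosting rounds and learning rate are defaults, not tuned; cohort-scale
  discrimination numbers therefore depend on these conventions.
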