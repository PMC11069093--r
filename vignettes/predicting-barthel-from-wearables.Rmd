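---
title: "Predicting the Barthel Index from wearable step counts: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting the Barthel Index from wearable step counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(watbarthel)
```

## The problem

The Barthel Index (BI) measures independence in basic activities of daily
living on a 0–100 scale in steps of 5; 0 is full dependence, 100 full
independence. For patients with complex chronic diseases it is one of the
strongest prognostic markers available, but it requires a clinical
assessment. A wrist activity tracker, by contrast, records steps and heart
rate continuously. `watbarthel` implements a pipeline that estimates the BI
— and its dependence class A (BI ≤ 20), B (20 < BI ≤ 60), C (BI > 60) —
from the last 30 days of tracker data, so functional status can be followed
between encounters.

Two properties of this population drive the design. First, activity comes
in short bursts that rarely last beyond an hour and cluster around the
daily meal routine; a segment's *maximum* hourly step count therefore
summarises it better than its sum or mean, which dilute a genuine burst
over many idle hours. Second, wrist devices undercount steps when gait is
assisted — most severely in wheelchair users — so the walking-aid group
enters the model as three indicator variables rather than pretending the
step counts are comparable across groups.

## Preprocessing model

Raw samples are processed in a fixed order:

1. **Missing-heart-rate nulling.** An interval without a heart-rate reading
   is interpreted as "device not worn"; its step count (an automatic 0) is
   set to missing rather than kept. By default this is applied at hourly
   granularity — an hour whose median heart rate is missing is nulled —
   with a per-sample variant available (`null_granularity = "sample"`).
2. **Hourly aggregation.** Steps are summed and heart rates reduced to
   their median within each (patient, day, hour).
3. **Smoothing.** The chronological hourly series is smoothed with a
   centered rolling mean of width 3 *before* any grouping by hour of day,
   so the smoother sees real temporal neighbours (including across
   midnight).
4. **Hour-of-day averaging.** Smoothed values are averaged per hour of day
   over a 30-day window ending the day before the encounter (half-open:
   the encounter day itself is excluded), producing a 24-value profile.
5. **Sufficiency filter.** A patient needs at least 14 distinct days with
   any non-missing data in the window; otherwise the patient is excluded
   via a typed condition (`watbarthel_insufficient_data`), never silently
   zero-filled.

Three numerical choices here were genuinely open and are worth recording:

* **Window edges.** The first and last element of the series use the one
  neighbour they have (a 2-point mean) instead of being dropped or
  NA-padded; dropping them would discard the first and last hour of every
  patient's record.
* **Missing values are never imputed.** A missing hour stays missing after
  smoothing (its neighbours simply skip it), and hour-of-day means are
  computed over observed values only. Imputing 0 would conflate "device
  not worn" with "no movement" — exactly the confusion the heart-rate rule
  exists to avoid.
* **A day counts toward the 14-day minimum** if it has at least one
  non-missing hourly record; day-level sufficiency has no natural stricter
  definition at this sampling density.

## Features

The profile is reduced to four segment maxima — morning 07–13 h, afternoon
14–19 h, evening 20–23 h, overnight 00–06 h, each listed hour an inclusive
hourly bin so the segments partition the 24 hours exactly — plus the
one-hot walking-aid block. Caregiver-assisted walking is coded
`cane_or_walker`: a caregiver supports gait the way a walker does, and a
three-group scheme keeps every group large enough to stratify on. `sum`
and `mean` reducers are available behind the same interface for
comparison, but `max` is the default for the burst-structure reason above.
Features are left unscaled: trees are invariant to monotone feature
scaling, and raw step units keep every split threshold interpretable.

## The regression tree

The model is a variance-reduction regression tree: greedy binary recursive
partitioning where each node chooses, among all features and all midpoints
between consecutive distinct feature values, the split minimising the
children's summed squared error. A split is accepted only if its *weighted*
impurity decrease — `(SSE_node − SSE_children) / n_total`, i.e. the node's
MSE reduction scaled by the node's share of the training set — reaches
`min_impurity_decrease`, and only if both children hold at least
`min_samples_leaf` rows. Leaves predict their training mean, so predictions
are always inside the training target range. A regression-then-classify
design is used rather than a direct 3-class classifier because the BI is
continuous: near a class boundary a 5-point error flips the label, and the
regression loss keeps gradations of error visible to model selection.

Determinism mattered more than elegance in two places:

* **Tie-breaking.** Split-quality ties (within an absolute tolerance of
  1e-9 in SSE units) resolve to the lowest feature index, then the lowest
  threshold. Fits are bit-reproducible and the exhaustive brute-force
  oracle in the test suite applies the identical rule.
* **Grid semantics.** The cross-validation grid spans
  `min_impurity_decrease` 0–1 in steps of 0.01, `min_samples_leaf` 1–10,
  and `min_samples_split` 1–10. A `min_samples_split` of 1 cannot yield a
  binary split; it is clamped to 2 with a warning rather than rejected, so
  the stated 10,100-point grid remains evaluable in full.

Model selection is 7-fold cross-validation with negative mean squared
error as the default score (negative median absolute error is available,
and is arguably the better headline metric for noisy step data; MSE is the
default because it is the convention model selection is usually tuned
under, and because MAD's plateaus create large score ties on small folds).
Among tied candidates the lexicographically smallest
(`min_impurity_decrease`, `min_samples_leaf`, `min_samples_split`) tuple
wins. One implementation point: because the chosen split never depends on
`min_impurity_decrease` — the parameter only gates whether the best split
is accepted — a tree constrained at level *m* equals the unconstrained
tree pruned at nodes whose recorded decrease falls below *m*. The CV loop
therefore fits one tree per fold per (`min_samples_leaf`,
`min_samples_split`) pair and sweeps all 101 `min_impurity_decrease`
values by pruning, which is exactly equivalent to refitting (the test
suite verifies this equivalence directly) and ~100× faster.

`max_depth` is deliberately *not* in the grid — depth is an outcome of the
other constraints, not a tuned quantity — but is exposed as an optional
cap. Rows tagged `role = "test"` (production-like profiles from a later
encounter) are refused by `fit_tree()`, enforcing that the test set never
leaks into training or selection.

## Evaluation

`regression_metrics()` reports MAE, median absolute error (MAD), RMSE and
R². `bi_to_class()` applies the A/B/C cutoffs identically to measured and
predicted (possibly non-integer) values; `classification_report()` returns
the 3×3 confusion matrix, per-class precision/recall/F1 and accuracy.
Undefined precision or recall (a class never predicted, or absent from the
data) reports 0.00 with a warning — with few class-A patients that outcome
is legitimate and should be visible, not an error. Permutation importance
is the decrease in R² when a single feature column is shuffled, repeated
(default 50×) to give a distribution per feature; it is computed on train,
validation and test sets alike, since the three baselines answer different
questions (memorisation vs. generalisation).

## The synthetic cohort generator

No clinical actigraphy ships with the package; `generate_cohort()` emulates
the data-generating process the pipeline assumes so that every stage can
be exercised and property-tested:

* **Cohort structure.** Class mix defaults to 1/9 A, 4/9 B, 4/9 C (a
  90-patient cohort with 10/40/40); the BI is uniform on the class grid of
  multiples of 5. The walking-aid mix is conditional on class — wheelchairs
  dominate class A, unaided walking dominates class C — with marginals
  near 58% none / 25% cane-walker-caregiver / 17% wheelchair.
* **Activity.** Per day, a Poisson number of bursts (class-dependent rate
  2/4/6); burst start hours are normal around meal anchors 9 h, 14 h,
  21 h (SD 1.25 h); burst length is 1 hour with probability 0.75, else 2 —
  a truncated geometric encoding "rarely beyond an hour". Steps per
  burst-hour scale with class and, within class, linearly with the true BI
  (factor 0.3–1.7 from BI 0 to 100), making mean daily steps monotone in
  BI.
* **Device effects.** Recorded steps are a binomial thinning of true steps
  with retention 1.0 / 0.6 / 0.15 for none / cane-or-walker / wheelchair —
  the attenuation that motivates the aid-group covariates. Heart-rate
  samples go missing with probability 0.05; with probability 0.1 a patient
  stops recording at a uniformly random point, which is what produces
  patients failing the 14-day rule.
* **Sampling.** 1-minute resolution by default. Real trackers differ in
  raw resolution and step-detection algorithms; hourly aggregation makes
  the pipeline insensitive to this, and the interval is configurable.

What the generator does *not* emulate — and what green tests therefore do
not establish about real data: sleep structure, heart-rate dynamics beyond
a burst-linked offset, device-specific step-detection artefacts,
within-patient BI change over time, and any correlation between dropout
and deterioration (dropout is missing-completely-at-random here, whereas
clinically it is driven by death and bedridden status, i.e. informative).
Passing tests demonstrate that the machinery is correct, not that the
model generalises to a clinical cohort.

## Problem sizes

The test suite works at deliberately modest scales chosen to probe each
property: oracle equivalence on 100 random tables of ≤ 12 rows (where
exhaustive enumeration is exact), profile equivalence against a
brute-force day/hour oracle on 50 synthetic patients of 16 days,
statistical-structure checks on a 200-patient × 8-day cohort, and
parameter recovery — a noiseless 3-level step dependence of BI on
`evening_max`, which the cross-validated tree must recover with validation
R² > 0.95 — on 300 patients with the full 10,100-candidate grid. The
acceptance script runs the complete pipeline on a 90-patient × 30-day
cohort (≈ 3.9 M raw samples) plus a 25-patient production-like test
cohort.

## Known limitations

* The split-unit question is left to the caller: the pipeline splits rows
  of whatever modeling table it is given. If patients contribute profiles
  at several encounters, rows from one patient can land on both sides of
  the split; stratification is by walking-aid group only.
* `min_impurity_decrease` is compared on the weighted (node-share) scale,
  which depends on the training-set size; the same grid value means a
  different absolute SSE threshold at different n.
* The 3-point smoother and the hourly grid are fixed design constants of
  the method, not tunables.
* Heart rate is used only for wear-time inference; exploiting step/heart-
  rate cross-correlation is out of scope.
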