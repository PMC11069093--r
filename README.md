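# watbarthel

Predicting the Barthel Index from wearable-activity-tracker step counts.

The Barthel Index (BI) scores independence in activities of daily living on
a 0–100 scale (steps of 5) and is a standard functional-status instrument
for patients with complex chronic disease. Measuring it requires a clinical
assessment; `watbarthel` estimates it continuously instead, from the
step-count stream of an ordinary wrist activity tracker, and maps the
estimate to the clinical dependence classes

* **A** — total dependence, BI ≤ 20,
* **B** — severe dependence, 20 < BI ≤ 60,
* **C** — moderate/mild dependence or independent, BI > 60.

It is written for biostatisticians and digital-health researchers working
with actigraphy from frail, mostly elderly cohorts, where activity comes in
short bursts (rarely longer than an hour), anchors to the daily meal
routine, and is systematically undercounted by wrist devices when the
patient walks with a cane, a walker, a caregiver's help, or uses a
wheelchair.

## The method

1. **Preprocessing.** Raw samples (steps, heart rate) are quality-filtered —
   an interval with no heart-rate reading has its steps nulled, since the
   device was not worn — aggregated to hourly sums, smoothed with a
   centered 3-point rolling mean, and averaged by hour of day over a 30-day
   look-back window before the clinical encounter. Patients with fewer than
   14 days of data are excluded. The result is a 24-value mean activity
   profile per patient.
2. **Features.** The profile is reduced to the maximum smoothed hourly step
   count in four segments — morning (07–13 h), afternoon (14–19 h), evening
   (20–23 h), overnight (00–06 h) — plus three walking-aid indicators
   (`no_walking_aid`, `cane_or_walker`, `wheelchair`).
3. **Model.** A regression tree fitted by greedy binary partitioning that
   minimises within-node squared error of the BI. Hyperparameters
   (`min_impurity_decrease` 0–1 by 0.01, `min_samples_leaf` 1–10,
   `min_samples_split` 1–10; 10,100 candidates) are selected by 7-fold
   cross-validation. The tree is deliberately interpretable: every node
   shows its split, sample size, and squared error.
4. **Evaluation.** MAE, median absolute error (MAD — the preferred metric
   for noisy step data), RMSE, and R²; predicted BI values are converted to
   A/B/C classes for accuracy, per-class precision/recall/F1, and confusion
   matrices. Permutation importance (decrease in R² when one feature is
   shuffled) explains the fitted model.

Because clinical actigraphy of this kind is rarely shareable, the package
includes a synthetic cohort generator (`sim_config()`, `generate_cohort()`)
that reproduces the statistical structure the pipeline assumes — burst
timing anchored to meal hours, BI-dependent activity amplitude, aid-group
step attenuation, heart-rate-linked missingness, early dropout — so every
stage is testable end to end.

## Worked example

```r
library(watbarthel)

cfg <- pipeline_config(
  simulate = sim_config(n_patients = 60, days_recorded = 30, seed = 42),
  seed = 1)
res <- run_pipeline(cfg, "out")

res$manifest$counts
#> $patients_input: 60   $profiles: 58   $excluded_min_days: 2
#> $train: 41            $validation: 17

print(res$evaluations$validation)
#> Evaluation on 17 records
#>   Accuracy  100%
#>   MAE       9.90
#>   MAD       7.50
#>   RMSE      12.50
#> Per-class metrics:
#>   class A: precision 1.00, recall 1.00, F1 1.00 (support 2)
#>   class B: precision 1.00, recall 1.00, F1 1.00 (support 6)
#>   class C: precision 1.00, recall 1.00, F1 1.00 (support 9)

head(res$importance$validation$summary, 3)
#> # A tibble: 3 × 2
#>   feature       mean_importance
#> 1 afternoon_max          1.38
#> 2 morning_max            0.0239
#> 3 overnight_max          0.0144
```

Two of the 60 simulated patients recorded fewer than 14 days and are
excluded; the 58 profiles split 41/17 while preserving walking-aid
proportions. Cross-validation selected `min_impurity_decrease = 0.55`,
`min_samples_leaf = 2`, `min_samples_split = 7`. The validation MAD of 7.5
BI points means the typical prediction is within 1–2 instrument steps of
the measured BI, and every validation patient lands in the correct
dependence class. `print(res$model)` renders the fitted tree with each
node's threshold, sample size, and squared error; `out/` holds
`profiles.csv`, `features.csv`, `model.json`, `report.json`, and a
`manifest.json` with the config hash and per-stage row counts.

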