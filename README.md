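# icuflow

Tools for studying **discharge readiness of cardiovascular patients in
intensive care units**: a synthetic, MIMIC-shaped cohort generator, a
discrete-time ward-flow model of bed occupancy and inspection-driven
discharges, and a regression pipeline (imputation, encoding, a
gradient-boosted/linear/blender model zoo, partition experiments) that
predicts the remaining days until a patient leaves the ICU ward.

It is aimed at researchers who want to prototype and stress-test
discharge-prediction pipelines without access to a credential-gated
critical-care EHR: every stage runs on data the package generates itself,
with known ground truth.

## What it computes

**Cohort.** `generate_cohort(default_config())` emits five relational
tables (PATIENTS, ADMISSIONS, ICUSTAYS, PRESCRIPTIONS, CHARTEVENTS) for a
cardiovascular ICU cohort of 4402 admissions over 4226 patients —
emergency/elective/urgent admissions 2804/1466/132; coronary artery
disease / congestive heart failure / acute coronary syndrome diagnoses
2808/1315/279 with 54/175/22 deaths at discharge; seventeen drug-class
exposures; mean age 65 y; mean ICU stay 2.9 d. Integer marginals are
allocated exactly, percentage marginals by largest-remainder counts, and
`cohort_summary()` recounts them all from the tables.

**Ward flow.** With wards `q = 1..M`, beds `w_q`, and patients of
pathology `k`, the model tracks the occupancy matrix
`U[q,k] = patients(q,k) / w_q`, free beds `F_q`, the primary
hospitalization rate `alpha_k = sum_{q: pref(q)=k} U[q,k] / (sum U + sum F)`
and its secondary complement, an allocation rule (preferred ward first,
then alternatives proportional to free capacity, then a FIFO overflow
queue), and Bernoulli discharges at each of the day's inspections with
`p = 1 / (mean LOS x inspections/day)`, so sojourns are geometric with
mean `1/p`. Cumulative discharges `Gamma_N = sum_n xi_n` and the exact
conservation identity (arrivals = in beds + discharged + queued) hold at
every epoch.

**Prediction.** The target is the remaining time (days, clipped to a
7-day horizon) from ICU admission to ward out-time. The generator plants
this signal as a weighted function of discharge location > diagnosis >
admission location > drug class > scheduled transfer hour > episode
length, plus 0.25 d Gaussian noise — so split-gain feature importance and
model accuracy have a known right answer. The zoo covers a depth-10
decision tree, three early-stopped gradient-boosted variants, an
auto-tuned SGD linear regressor, and three stacked blenders (ridge
meta-learner, 16-unit neural meta-learner, unweighted average). Metrics
are the residual mean (RMSE, days) and accuracy (share of predictions
within 1 day).

## Worked example

```r
library(icuflow)

bundle <- generate_cohort(default_config())
s <- cohort_summary(bundle)
s$admission_type_counts["EMERGENCY"]   #> 2804
round(s$mean_los_days["overall"], 1)   #> 2.9

feats <- build_features(inject_missingness(bundle, 0.3, seed = 1))
enc   <- encode_categoricals(feats)
parts <- make_partitions(enc$table, partition_config(18, 36, 72, seed = 1))
m  <- fit_model(model_spec("blend_glrm", params = list(nrounds = 300)),
                enc$table[parts$holdout$train, ])
ev <- evaluate_predictions(predict(m, enc$table[parts$holdout$test, ]),
                           enc$table$target_days[parts$holdout$test])
round(ev$residual_mean, 2)             #> 0.29
round(ev$accuracy, 2)                  #> 1
```

The holdout residual mean (~0.29 d) sits just above the planted 0.25 d
noise floor, and essentially every prediction lands within the 1-day
accuracy band; the split-gain ranking from
`feature_importance(fit_model(model_spec("gbm_light"), enc$table))` puts
discharge location first (100%), then diagnosis, then admission location
— the planted ordering.

## Analysis workflow

Numbered drivers under `analysis/` run the study end to end, writing
tables to `results/`:

| script | what it does |
|---|---|
| `01_generate_cohort.R` | generate + validate the cohort, recount marginals |
| `02_flow_simulation.R` | 360-epoch ward-flow run, conservation and sojourn checks |
| `03_preprocess.R` | missingness injection, backfill, imputation, encoding |
| `04_models.R` | model zoo on the holdout protocol + grid search + importances |
| `05_experiments.R` | the four partition experiments x model zoo report |

`run_pipeline()` chains the same stages programmatically from one YAML
config with a single root seed and writes a manifest of artifact hashes.

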