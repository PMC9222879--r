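---
title: "icuflow: methods and modeling choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{icuflow: methods and modeling choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Deciding when an ICU patient is ready to leave their ward couples two
questions: a *flow* question (how beds, arrivals and discharge
inspections interact across wards) and a *prediction* question (how many
days remain until this patient's ward stay ends). `icuflow` implements
both over a synthetic electronic-health-record cohort shaped like the
public critical-care databases used in this literature, so that every
stage — generation, validation, simulation, preprocessing, model fitting,
evaluation — is reproducible and testable against known ground truth
without any credentialed data access.

## The synthetic cohort

### What is emulated

`default_config()` transcribes the baseline characteristics of a
cardiovascular ICU cohort: 4402 admissions over 4226 patients (176
subjects contribute exactly two admissions each); admission routes
2804/1466/132 (emergency/elective/urgent); diagnosis groups 2808/1315/279
(coronary artery disease, congestive heart failure, acute coronary
syndrome) with 54/175/22 deaths at discharge; seventeen prescription drug
classes with exposure shares between 0.15% and 14.62%; mean age 65 y, 53%
men; mean ICU stay 2.9 d overall and 3.1 d among those dead at discharge.

Integer marginals are allocated *exactly*: diagnosis and vital-status
labels are laid out deterministically and then permuted, and the joint
(route x vital status) allocation honors both margins. Percentage
marginals use largest-remainder counts, the closest an integer allocation
can come to the printed share. One printed share (0.15% of 4402) has no
integer realization at its printed precision — no count lands within
rounding distance — so the round-trip contract is "within half a count"
for shares, and exact for every integer marginal.

Three source-table inconsistencies are resolved in favor of the overall
and dead counts (alive = overall − dead), since the dead counts drive the
mortality stratification and the overall counts the totals. Similarly,
the dead/alive stay sub-means are jointly incompatible with the overall
mean under the printed group sizes; the overall (2.9 d) and dead (3.1 d)
means are enforced by group-wise recentering and the alive mean is the
implied remainder (≈2.89 d).

The "length of stay" the configuration governs is the LOS column of the
ICU-stay table: the stay in the one ward whose end is the modeled
discharge (any transfer counts as a discharge). The surrounding hospital
episode — admission-to-ICU delay (uniform 0–1 d), the ICU stay, and a
post-ICU ward tail (gamma, shape 0.4, scale 25 d) — is deliberately
longer and much noisier; see below for why.

De-identification is mirrored by placing all dates in a shifted 2100–2200
window; a readmitted subject's second admission always starts after their
first discharge, and nobody is readmitted after dying.

### The planted discharge-readiness signal

The ICU stay is generated as

```
los = recenter( w_dl·s(discharge_location) + w_dx·s(diagnosis)
              + w_al·s(admission_location) + w_rx·s(drug class)
              + w_out·s(transfer hour)     + w_tail·s(ward tail)
              + Normal(0, 0.25 d) ),  clipped to [0.2, 7] d
```

with weights `2.0 > 1.0 > 0.6 > 0.35 > 0.2 > 0.12` and per-level scores
in roughly [−1, 1]. The weight ladder is chosen so the variance each
block contributes is cleanly separated (≈1.7, 0.6, 0.073, 0.036, 0.013
squared days for the first five), which makes the split-gain importance
ranking of a boosted-tree fit recover the intended ordering — discharge
location, then diagnosis, then admission location — reliably at the
default cohort size. `recenter` shifts the dead and alive groups to their
configured means (a location shift, so it does not disturb the
within-group effect structure).

One design constraint deserves emphasis: the hospital-episode length
*must not* additively contain the ICU stay at comparable scale, or the
LOS feature trivially encodes the regression target and tops every
importance ranking. This is why the post-ICU tail is long and
heavy-tailed (mean ≈10 d, sd ≈16 d): the episode remains temporally
coherent (admit < ICU-in < ICU-out < discharge) while the ICU stay
explains only ~1% of the episode's variance, keeping the LOS feature
informative but subordinate.

### What the generator does *not* emulate

Vitals are i.i.d. draws around their configured means (no trends, no
severity coupling); each admission has exactly one ICU stay; drug
exposures are independent across classes; and the discharge-readiness
signal is additive with Gaussian noise. Tests passing on this cohort
therefore certify the *machinery* — exact marginals, leakage-free
plumbing, metric correctness, recoverability of a known signal — not
clinical validity on real EHR data, where feature effects are neither
additive nor stationary and missingness is informative.

### Missingness

`inject_missingness()` withholds a largest-remainder-exact fraction of
non-invasive blood-pressure readings (ground truth retained), while the
paired invasive channel stays observed — mirroring the real recording
asymmetry between the two pressure channels. `backfill_nibp()` restores
them from the invasive reading plus a calibration offset (default 0; the
generator makes the channels agree exactly at paired timestamps, so the
round trip is exact by construction). Readings missing in both channels
fall through to median imputation.

## The ward-flow model

Time advances in inspection epochs (default 3/day). The state is a
per-patient roster (ward, pathology, sojourn clock), a FIFO overflow
queue, and the discharge ledger.

* **Occupancy** `U[q,k]` is patients of pathology `k` in ward `q` over
  that ward's beds; a zero-bed ward has occupancy 0 by convention (with a
  warning).
* **Rates.** The distribution mass is the occupancy block together with
  the free-bed vector, `D = sum(U) + sum(F)`. The primary rate
  `alpha_k` is the preferred-ward occupancy share of `D`. The secondary
  rate as written in this formulation is the *remaining* mass share —
  which under that same definition of `D` is never positive once free
  beds are counted, so `beta` is clamped to [0, 1] with a `clamped`
  attribute recording when clamping fired. Secondary hospitalization is
  realized operationally by the allocation rule rather than by `beta`
  itself, which avoids double-counting the same mechanism. `flow_rates()`
  errors when no patient occupies any bed (the rates describe patients,
  and an all-empty system has none to describe).
* **Allocation.** Arrivals of pathology `k` fill the preferred ward while
  it has beds; the remainder spreads over alternative wards
  proportionally to free capacity (largest remainder, ties to the lowest
  ward index — deterministic and capacity-aware); anyone left joins the
  overflow queue, which is retried FIFO before new arrivals each epoch.
* **Discharges.** At each inspection every in-bed patient leaves
  independently with probability `p_k`, calibrated as
  `1 / (mean LOS x inspections per day)` so the sojourn (in inspections)
  is geometric with the right mean. Per-epoch counts `xi` accumulate into
  `Gamma`, and the exact integer conservation identity
  `arrivals = in beds + Gamma + queued` is checked at every epoch.
* Sojourn clocks `tau` are tracked per patient and surfaced through the
  discharge ledger as a summary statistic; no update rule consumes them.

## Preprocessing

`build_features()` flattens the five tables to one row per ICU stay:
discharge location, diagnosis, admission location, primary drug class
(first exposed class in table order, `NONE` if unexposed), prescription
strength and start/end day-of-month, episode length, admission and ICU
in-hours, out-time day-of-month, scheduled ward-transfer hour,
first-admission flag, and per-stay vitals means. Imputation order:
invasive backfill, then per-column regression trees (depth 10, min leaf
4 — the baseline tree's settings) trained on observed rows in ascending
missingness order, then median for anything left. The returned table has
zero missing cells, and imputation never touches observed values.

Categoricals are ordinal-encoded in first-appearance order (codes from
0), with an invertible codebook; unseen levels at transform time get the
reserved code −1 with a warning. The "linear regularization" of
categorical handling is read as: ordinal codes, with L2 penalties applied
in the linear learners downstream. An optional correlation screen
(`drop_correlated()`, |r| > 0.95) is provided but not part of the default
path. Split-gain importances are reported both rescaled to a 100% top
feature (the convention in this literature's figures) and normalized to
sum to one.

## The model zoo

Eight regressors, all predicting days-to-discharge clipped to a 7-day
horizon:

| family | implementation | key settings |
|---|---|---|
| `decision_tree` | rpart (squared error) | depth 10, min leaf 4, min split 10 |
| `gbm_extreme` | xgboost, exact splits, L2-regularized objective | 2000 rounds cap, eta 0.3, min child 2 |
| `gbm_greedy` | xgboost, exact greedy splits, no L2 | same |
| `gbm_light` | xgboost, histogram binning | same |
| `sgd_linear` | hand-written mini-batch SGD | lr grid {1e-3,1e-2,1e-1} x {L2, elastic-net}, chosen on a 10% slice |
| `blend_glrm` | ridge meta-learner over base predictions | closed form, lambda 1e-3 |
| `blend_enet` | single-hidden-layer (16 unit) meta-learner | nnet, early decay |
| `blend_avg` | unweighted mean of bases | exact by definition |

A tree "entropy" criterion is meaningless for regression, so the
baseline tree uses squared error. Boosted fits hold out a random 10%
slice and stop after 50 stagnant rounds, keeping the best checkpoint —
the selected iteration's validation error is by construction no worse
than the final iteration's. Blenders stack a 75/25 internal split: bases
learn on the 75%, the meta-learner on their out-of-sample predictions,
and the bases are then refit on the full table for deployment. Accuracy
is the share of predictions within a tolerance that must be declared for
a regressor; the default is 1 day.

`grid_search()` is exhaustive, minimizes validation residual mean (RMSE),
and breaks ties toward fewer estimators, then shallower trees.

## Partition experiments

The three evaluation percentages of each experiment sum past 100, so they
cannot be one disjoint split; they are three *protocols* over the same
table: a random validation split at the stated share, k-fold
cross-validation (k = 5) restricted to a random subset of the stated
share, and a holdout protocol whose training pool is the stated share
with the complement as test set. This reading matches the row structure
of the reported results (separate residual-mean rows per protocol) and is
isolated in `make_partitions()` should a different reading be preferred.
Accuracy is reported from the holdout protocol (training-side accuracy is
also computed); wall times are informational only and never asserted.

## Numerical choices and degenerate inputs

* Slice sizes everywhere are largest-remainder roundings, so counts are
  exact and sum correctly; remainder ties break to the lower index.
* Predictions are clipped to [0, 7] days; generated stays to [0.2, 7].
* All stage seeds derive from one root seed (`derive_seed`), kept below
  2^31; identical (config, seed) reruns are byte-identical for data
  artifacts, verified by manifest hashes.
* Timestamps are whole seconds so CSV round trips preserve every interval
  and the stored LOS equals the in/out difference exactly (tolerance
  1e-6 d in the validator).
* Empty cases: a zero-admission config yields empty, schema-complete
  tables; an empty prediction table yields an empty prediction; empty
  metric inputs, all-missing columns, empty grids and infeasible
  partitions raise errors naming the problem.
* Stochastic test checks (binomial inspection counts, the geometric
  sojourn distribution) use closed-form nulls; the sojourn check uses a
  sup-distance statistic over the integer support against a Monte-Carlo
  geometric null, since the classical one-sample test is invalid under
  heavy ties, and takes a 2-of-3 majority over simulation seeds at
  alpha = 0.01 each so a single 1%-tail seed cannot flip the verdict
  either way.

## Problem sizes

The default test suite exercises the full 4402-admission cohort for the
marginal and signal-recovery checks (20 importance replicates, one
blender holdout fit), 1000-epoch flow trajectories over 10 seeds, a
10,000-sample sojourn comparison, and small synthetic tables (100–400
rows) for the model-level oracles; the analysis drivers default to a
four-model zoo at a 150-round boosting cap, with the full eight-family
zoo behind a flag. These sizes were chosen as the smallest at which the
statistical checks are well-powered.

## Known limitations

* The secondary-rate formula is degenerate under the stated mass
  definition (always clamped to 0 when free beds exist); the allocation
  rule carries the secondary-hospitalization semantics.
* The planted signal is additive and stationary; real discharge decisions
  are neither, so model rankings here need not transfer to real cohorts.
* Vitals carry no within-stay dynamics, and only per-stay means enter the
  feature table; time-series featurization is out of scope.
* The neural meta-learner is a small fixed architecture, not a tuned deep
  model; it exists to complete the blender family, not to compete.
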