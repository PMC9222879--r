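#' Recompute baseline-table marginals from a generated bundle
#'
#' Recounts every marginal of the baseline characteristics table directly
#' from the relational tables: admission totals, distinct subjects,
#' admission routes, diagnosis groups, deaths by diagnosis, per-drug-class
#' exposure and dead-at-discharge shares, mean age, percent men, and the
#' mean length of stay (the LOS column of the ICU-stay table) overall /
#' dead / alive, plus the mean hospital-episode span. This is the acceptance
#' surface: for any feasible configuration the summary of
#' `generate_cohort(config)` reproduces the integer marginals exactly.
#'
#' @param bundle An `ehr_bundle`.
#' @return A list shaped like a [cohort_config()]: counts, a
#'   `drug_class_rows` data frame with recomputed percentages, and the
#'   continuous summaries.
#' @export
cohort_summary <- function(bundle) {
  stopifnot(inherits(bundle, "ehr_bundle"))
  adm <- bundle$admissions
  n <- nrow(adm)
  dead <- adm$hospital_expire_flag == 1L

  count_by <- function(x, dead_mask = NULL) {
    if (n == 0) return(stats::setNames(integer(0), character(0)))
    lv <- unique(x)
    sel <- if (is.null(dead_mask)) rep(TRUE, n) else dead_mask
    stats::setNames(vapply(lv, function(l) sum(x == l & sel), 1L), lv)
  }

  pres <- bundle$prescriptions
  classes <- unique(pres$drug_class)
  drug_rows <- data.frame(class = character(0), pct_overall = numeric(0),
                          pct_dead = numeric(0), n_exposed = integer(0),
                          n_dead_exposed = integer(0))
  if (length(classes) > 0 && n > 0) {
    dead_hadm <- adm$hadm_id[dead]
    drug_rows <- do.call(rbind, lapply(classes, function(cl) {
      exposed <- unique(pres$hadm_id[pres$drug_class == cl])
      nd <- sum(exposed %in% dead_hadm)
      data.frame(class = cl,
                 pct_overall = 100 * length(exposed) / n,
                 pct_dead = if (length(exposed)) 100 * nd / length(exposed) else 0,
                 n_exposed = length(exposed), n_dead_exposed = nd)
    }))
  }

  # the LOS column of the ICU-stay table, aligned to its admission
  los_days <- if (n > 0) {
    bundle$icustays$los[match(adm$hadm_id, bundle$icustays$hadm_id)]
  } else numeric(0)

  list(
    n_admissions = n,
    n_patients = length(unique(bundle$patients$subject_id)),
    admission_type_counts = count_by(adm$admission_type),
    diagnosis_counts = count_by(adm$diagnosis),
    dead_by_diagnosis = count_by(adm$diagnosis, dead),
    dead_by_admission_type = count_by(adm$admission_type, dead),
    drug_class_rows = drug_rows,
    mean_age_overall = if (nrow(bundle$patients)) mean(bundle$patients$age) else NA_real_,
    pct_men = if (nrow(bundle$patients))
      100 * mean(bundle$patients$sex == "M") else NA_real_,
    mean_los_days = c(
      overall = if (n > 0) mean(los_days) else NA_real_,
      dead = if (any(dead)) mean(los_days[dead]) else NA_real_,
      alive = if (any(!dead)) mean(los_days[!dead]) else NA_real_
    ),
    mean_hospital_days = if (n > 0)
      mean(as.numeric(difftime(adm$discharge_time, adm$admit_time,
                               units = "days"))) else NA_real_
  )
}

#' Validate referential and temporal integrity of an EHR bundle
#'
#' Checks the relational contract of the five tables: required columns;
#' one subject per admission and one admission per ICU stay; no orphan
#' keys; admission before discharge and ICU in-time before out-time; the
#' stored ICU length of stay equal to the in/out interval; and all dates
#' inside the shifted 2100-2200 de-identification window.
#'
#' @param bundle An `ehr_bundle` (or a directory path readable by
#'   [read_bundle()]).
#' @return A data frame of violations (`table`, `rule`, `id`, `detail`);
#'   zero rows means the bundle is clean.
#' @export
validate_bundle <- function(bundle) {
  if (is.character(bundle)) bundle <- read_bundle(bundle)
  stopifnot(inherits(bundle, "ehr_bundle"))
  v <- list()
  bad <- function(table, rule, id, detail)
    data.frame(table = table, rule = rule, id = as.character(id),
               detail = detail, stringsAsFactors = FALSE)

  required <- list(
    patients = c("subject_id", "sex", "age", "dead_flag"),
    admissions = c("subject_id", "hadm_id", "admission_type", "admit_time",
                   "discharge_time", "diagnosis", "admission_location",
                   "discharge_location"),
    icustays = c("hadm_id", "icustay_id", "in_time", "out_time", "los",
                 "ward_id"),
    prescriptions = c("hadm_id", "drug", "drug_class", "start_date",
                      "end_date", "prod_strength", "frequency"),
    chartevents = c("icustay_id", "item", "time", "value", "missing_flag")
  )
  for (tb in names(required)) {
    miss <- setdiff(required[[tb]], names(bundle[[tb]]))
    if (length(miss))
      v[[length(v) + 1L]] <- bad(tb, "missing_column", "-",
                                 paste(miss, collapse = ", "))
  }
  if (length(v)) return(do.call(rbind, v))  # schema broken: stop here

  adm <- bundle$admissions; icu <- bundle$icustays
  if (anyDuplicated(adm$hadm_id))
    v[[length(v) + 1L]] <- bad("admissions", "duplicate_hadm_id",
                               adm$hadm_id[duplicated(adm$hadm_id)][1], "")
  if (anyDuplicated(icu$icustay_id))
    v[[length(v) + 1L]] <- bad("icustays", "duplicate_icustay_id",
                               icu$icustay_id[duplicated(icu$icustay_id)][1], "")
  orphan_subj <- setdiff(adm$subject_id, bundle$patients$subject_id)
  for (s in orphan_subj)
    v[[length(v) + 1L]] <- bad("admissions", "orphan_subject_id", s,
                               "no such subject in patients")
  orphan_hadm <- setdiff(icu$hadm_id, adm$hadm_id)
  for (h in orphan_hadm)
    v[[length(v) + 1L]] <- bad("icustays", "orphan_hadm_id", h,
                               "no such admission")
  orphan_rx <- setdiff(bundle$prescriptions$hadm_id, adm$hadm_id)
  for (h in orphan_rx)
    v[[length(v) + 1L]] <- bad("prescriptions", "orphan_hadm_id", h,
                               "no such admission")
  orphan_ce <- setdiff(bundle$chartevents$icustay_id, icu$icustay_id)
  for (s in unique(orphan_ce))
    v[[length(v) + 1L]] <- bad("chartevents", "orphan_icustay_id", s,
                               "no such ICU stay")

  rev_adm <- which(!(adm$admit_time < adm$discharge_time))
  for (i in rev_adm)
    v[[length(v) + 1L]] <- bad("admissions", "reversed_interval",
                               adm$hadm_id[i], "DISCHTIME <= ADMITTIME")
  rev_icu <- which(!(icu$in_time < icu$out_time))
  for (i in rev_icu)
    v[[length(v) + 1L]] <- bad("icustays", "reversed_interval",
                               icu$icustay_id[i], "OUTTIME <= INTIME")
  los_chk <- abs(as.numeric(difftime(icu$out_time, icu$in_time,
                                     units = "days")) - icu$los)
  for (i in which(los_chk > 1e-6))
    v[[length(v) + 1L]] <- bad("icustays", "los_mismatch", icu$icustay_id[i],
                               sprintf("stored %.4f vs interval", icu$los[i]))
  lo <- as.POSIXct("2100-01-01", tz = "UTC")
  hi <- as.POSIXct("2200-12-31", tz = "UTC")
  if (nrow(adm) && (any(adm$admit_time < lo) || any(adm$discharge_time > hi)))
    v[[length(v) + 1L]] <- bad("admissions", "date_window", "-",
                               "dates outside the shifted 2100-2200 window")
  if (length(v) == 0)
    return(data.frame(table = character(0), rule = character(0),
                      id = character(0), detail = character(0)))
  do.call(rbind, v)
}
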