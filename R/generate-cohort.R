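# Level-effect tables for the planted discharge-readiness signal. The
# relevance ladder (discharge location > diagnosis > admission location >
# drug class > scheduled out-hour > hospital LOS) is realized by giving
# each block a per-level score in roughly [-1, 1] and a decreasing weight,
# so the variance each block contributes to the ICU length of stay is
# cleanly separated.
SIGNAL_WEIGHTS <- c(discharge_location = 2.0, diagnosis = 1.0,
                    admission_location = 0.6, drug = 0.35,
                    out_hour = 0.2, los = 0.12)

DISCHARGE_LOCATIONS <- c("HOME", "HOME HEALTH CARE", "SNF",
                         "REHAB/DISTINCT PART HOSP",
                         "LONG TERM CARE HOSPITAL", "DEAD/EXPIRED")
DISCHARGE_LOC_SCORE <- c(
  "HOME" = -1, "HOME HEALTH CARE" = -0.6, "SNF" = 0.45,
  "REHAB/DISTINCT PART HOSP" = -0.1, "LONG TERM CARE HOSPITAL" = 1,
  "DEAD/EXPIRED" = 0
)
DISCHARGE_LOC_PROB_ALIVE <- c(0.38, 0.25, 0.18, 0.12, 0.07)

ADMISSION_LOCATIONS <- c("EMERGENCY ROOM ADMIT", "PHYS REFERRAL/NORMAL DELI",
                         "TRANSFER FROM HOSP/EXTRAM",
                         "CLINIC REFERRAL/PREMATURE")
ADMISSION_LOC_SCORE <- c(
  "EMERGENCY ROOM ADMIT" = 0.5, "PHYS REFERRAL/NORMAL DELI" = -1,
  "TRANSFER FROM HOSP/EXTRAM" = 1, "CLINIC REFERRAL/PREMATURE" = -0.2
)
ADMISSION_LOC_PROB <- list(
  EMERGENCY = c(0.72, 0.00, 0.18, 0.10),
  ELECTIVE  = c(0.00, 0.80, 0.05, 0.15),
  URGENT    = c(0.25, 0.00, 0.60, 0.15)
)

DIAGNOSIS_SCORE <- c(
  "CORONARY ARTERY DISEASE" = -0.6,
  "CONGESTIVE HEART FAILURE" = 0.9,
  "ACUTE CORONARY SYNDROME" = 1.4
)

# example generic drugs per class, for the PRESCRIPTIONS table
DRUG_EXAMPLES <- list(
  "Cholesterol lowering medications" = c("Atorvastatin", "Simvastatin"),
  "ACE inhibitors" = c("Lisinopril", "Captopril"),
  "Bronchodilators" = c("Albuterol", "Ipratropium Bromide"),
  "Diuretics" = c("Furosemide", "Hydrochlorothiazide"),
  "Insulins" = c("Insulin", "Insulin Human Regular"),
  "Anticoagulants" = c("Heparin", "Warfarin"),
  "Electrolytes" = c("Potassium Chloride", "Magnesium Sulfate"),
  "Beta blockers" = c("Metoprolol", "Carvedilol"),
  "Antiplatelet agents and DAPT" = c("Aspirin", "Clopidogrel"),
  "Anti-histamines" = c("Diphenhydramine", "Loratadine"),
  "Quinolone antibiotics" = c("Ciprofloxacin", "Levofloxacin"),
  "Nitrates" = c("Nitroglycerin", "Isosorbide Dinitrate"),
  "Peptides" = c("Vasopressin", "Octreotide"),
  "Glucose elevating agents" = c("Dextrose 50%", "Glucagon"),
  "Antidysrhythmics" = c("Amiodarone", "Lidocaine"),
  "Calcium channel blockers" = c("Diltiazem", "Amlodipine"),
  "Sulfonic acid" = c("Polystyrene Sulfonate", "Mesna")
)
PROD_STRENGTHS <- c("25mg Tablet", "50mg Tablet", "100mg Tablet",
                    "10mg/mL Vial", "5mg/5mL Solution", "40mg Capsule")
FREQUENCIES <- c("QD", "BID", "TID", "Q6H", "PRN")

CHART_ITEMS <- c("heart_rate", "resp_rate", "nibp", "ibp")

# scores per drug class, spread over [-1, 1] in class order; NONE = 0
drug_class_scores <- function(classes) {
  if (length(classes) == 0) return(c(NONE = 0))
  s <- seq(-1, 1, length.out = length(classes))
  stats::setNames(c(s, 0), c(classes, "NONE"))
}

empty_bundle <- function(config) {
  structure(list(
    patients = data.frame(subject_id = integer(0), sex = character(0),
                          age = numeric(0), dead_flag = logical(0)),
    admissions = data.frame(subject_id = integer(0), hadm_id = integer(0),
                            admission_type = character(0),
                            admit_time = as.POSIXct(character(0), tz = "UTC"),
                            discharge_time = as.POSIXct(character(0), tz = "UTC"),
                            diagnosis = character(0),
                            admission_location = character(0),
                            discharge_location = character(0),
                            hospital_expire_flag = integer(0)),
    icustays = data.frame(hadm_id = integer(0), icustay_id = integer(0),
                          in_time = as.POSIXct(character(0), tz = "UTC"),
                          out_time = as.POSIXct(character(0), tz = "UTC"),
                          los = numeric(0), ward_id = integer(0),
                          sched_ward_transfer_hour = integer(0)),
    prescriptions = data.frame(hadm_id = integer(0), drug = character(0),
                               drug_class = character(0),
                               start_date = as.POSIXct(character(0), tz = "UTC"),
                               end_date = as.POSIXct(character(0), tz = "UTC"),
                               prod_strength = character(0),
                               frequency = character(0)),
    chartevents = data.frame(icustay_id = integer(0), item = character(0),
                             time = as.POSIXct(character(0), tz = "UTC"),
                             value = numeric(0), missing_flag = logical(0))
  ), class = "ehr_bundle", config = config)
}

#' Generate a synthetic MIMIC-shaped ICU cohort
#'
#' Emits the five relational tables (patients, admissions, ICU stays,
#' prescriptions, chart events) of a cardiovascular ICU cohort. Integer
#' marginals of the configuration — admission routes, diagnosis groups,
#' deaths by diagnosis (and by route) — are allocated deterministically and
#' reproduce exactly; drug-class exposures use largest-remainder counts so
#' recomputed shares round back to the configured percentages wherever an
#' integer count can realize them. Ages are truncated-normal draws. The
#' hospital episode decomposes into an admission-to-ICU delay, the ICU
#' stay, and a long-tailed post-ICU ward tail; the configured mean stay
#' governs the LOS column of the ICU-stay table (the stay in the one ward
#' whose end is the modeled discharge), recentered group-wise so the
#' overall and dead-at-discharge means hold exactly.
#'
#' The ICU length of stay carries the planted discharge-readiness signal:
#' a weighted sum of level effects of discharge location, diagnosis,
#' admission location, primary drug class, the scheduled ward-transfer
#' hour and the ward-tail scale, plus Gaussian noise, clipped to [0.2, 7]
#' days. The weight ladder makes discharge location the most informative
#' feature, then diagnosis, then admission location.
#'
#' De-identification convention: all dates live in a shifted 2100-2200
#' window; a readmitted subject keeps a coherent timeline (second admission
#' after the first discharge).
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed; defaults to the seed stored in `config`.
#' @return An `ehr_bundle`: a named list of the five data frames, with the
#'   generating config attached as an attribute.
#' @examples
#' cfg <- default_config()
#' cfg$n_admissions <- 40L; cfg$n_patients <- 38L
#' cfg$admission_type_counts <- c(EMERGENCY = 25L, ELECTIVE = 13L, URGENT = 2L)
#' cfg$diagnosis_counts <- c("CORONARY ARTERY DISEASE" = 25L,
#'   "CONGESTIVE HEART FAILURE" = 12L, "ACUTE CORONARY SYNDROME" = 3L)
#' cfg$dead_by_diagnosis <- c("CORONARY ARTERY DISEASE" = 1L,
#'   "CONGESTIVE HEART FAILURE" = 2L, "ACUTE CORONARY SYNDROME" = 0L)
#' cfg$dead_by_admission_type <- NULL
#' b <- generate_cohort(cfg)
#' nrow(b$admissions)
#' @export
generate_cohort <- function(config, seed = config$seed) {
  validate_config(config)
  n <- config$n_admissions
  if (n == 0L) return(empty_bundle(config))
  set.seed(seed)

  dx_names <- names(config$diagnosis_counts)
  type_names <- names(config$admission_type_counts)

  ## ---- admission-level exact marginals ------------------------------
  diagnosis <- rep(dx_names, config$diagnosis_counts)
  dead <- logical(n)
  off <- 0L
  for (k in seq_along(dx_names)) {
    nd <- config$dead_by_diagnosis[[dx_names[k]]]
    if (nd > 0) dead[off + seq_len(nd)] <- TRUE
    off <- off + config$diagnosis_counts[[k]]
  }
  n_dead <- sum(dead)

  dead_by_type <- config$dead_by_admission_type
  if (is.null(dead_by_type)) {
    dead_by_type <- stats::setNames(
      largest_remainder(config$admission_type_counts, n_dead), type_names)
  }
  alive_by_type <- config$admission_type_counts - dead_by_type[type_names]
  admission_type <- character(n)
  admission_type[dead] <- rep(type_names, dead_by_type[type_names])
  admission_type[!dead] <- rep(type_names, alive_by_type)

  # shuffle rows so marginal blocks are not positionally confounded
  perm <- sample.int(n)
  diagnosis <- diagnosis[perm]
  dead <- dead[perm]
  admission_type <- admission_type[perm]

  ## ---- locations -----------------------------------------------------
  admission_location <- character(n)
  for (ty in type_names) {
    idx <- which(admission_type == ty)
    p <- ADMISSION_LOC_PROB[[ty]]
    if (is.null(p)) p <- rep(1 / length(ADMISSION_LOCATIONS),
                             length(ADMISSION_LOCATIONS))
    admission_location[idx] <- sample(ADMISSION_LOCATIONS, length(idx),
                                      replace = TRUE, prob = p)
  }
  discharge_location <- character(n)
  discharge_location[dead] <- "DEAD/EXPIRED"
  discharge_location[!dead] <- sample(DISCHARGE_LOCATIONS[1:5], n - n_dead,
                                      replace = TRUE,
                                      prob = DISCHARGE_LOC_PROB_ALIVE)

  ## ---- drug-class exposure (largest-remainder counts) ----------------
  drows <- config$drug_class_rows
  exposure <- vector("list", nrow(drows))
  dead_idx_all <- which(dead); alive_idx_all <- which(!dead)
  if (nrow(drows) > 0) for (i in seq_len(nrow(drows))) {
    n_exp <- lr_count(drows$pct_overall[i] / 100, n)
    n_exp_dead <- min(lr_count(drows$pct_dead[i] / 100, n_exp), n_dead)
    n_exp_alive <- min(n_exp - n_exp_dead, length(alive_idx_all))
    rows <- c(if (n_exp_dead > 0) sample(dead_idx_all, n_exp_dead),
              if (n_exp_alive > 0) sample(alive_idx_all, n_exp_alive))
    exposure[[i]] <- sort(rows)
  }
  # primary class per admission = first exposed class in table order
  primary_class <- rep("NONE", n)
  if (nrow(drows) > 0) for (i in rev(seq_len(nrow(drows)))) {
    primary_class[exposure[[i]]] <- drows$class[i]
  }

  ## ---- planted ICU length of stay (the discharge-readiness target) ---
  # the configured mean stay governs the LOS column of the ICU-stay table
  # (the stay in the one ward whose end is the modeled discharge); the
  # full hospital episode around it is longer and unconstrained.
  sched_out_hour <- sample(0:23, n, replace = TRUE)
  ward_tail <- pmax(stats::rgamma(n, shape = 0.4, scale = 25), 0.02)
  dscore <- drug_class_scores(drows$class)
  w <- SIGNAL_WEIGHTS
  icu_raw <-
    w[["discharge_location"]] * DISCHARGE_LOC_SCORE[discharge_location] +
    w[["diagnosis"]] * DIAGNOSIS_SCORE[diagnosis] +
    w[["admission_location"]] * ADMISSION_LOC_SCORE[admission_location] +
    w[["drug"]] * dscore[primary_class] +
    w[["out_hour"]] * (sched_out_hour - 11.5) / 11.5 +
    w[["los"]] * pmin(pmax((ward_tail - 10) / 10, -1.5), 1.5) +
    stats::rnorm(n, 0, config$signal_noise_sd)
  icu_raw <- unname(icu_raw)
  # group-wise recentering: dead stays average mean_los_days["dead"], the
  # alive mean is the remainder so the overall mean holds exactly
  m_overall <- config$mean_los_days[["overall"]]
  target_mean <- ifelse(dead,
                        config$mean_los_days[["dead"]],
                        if (n_dead < n)
                          (n * m_overall -
                             n_dead * config$mean_los_days[["dead"]]) /
                          (n - n_dead) else m_overall)
  icu_los <- icu_raw
  for (it in 1:4) {      # shift-and-clip: converges in a few passes
    for (g in list(dead, !dead)) {
      if (!any(g)) next
      icu_los[g] <- icu_los[g] + (target_mean[g][1] - mean(icu_los[g]))
    }
    icu_los <- pmin(pmax(icu_los, 0.2), 7)
  }

  ## ---- hospital stay = delay + ICU stay + post-ICU ward tail ----------
  delay <- stats::runif(n, 0, 1)            # admission-to-ICU, days
  hosp_los <- delay + icu_los + ward_tail

  ## ---- subjects and readmissions -------------------------------------
  n_extra <- n - config$n_patients
  alive_pool <- sample(alive_idx_all)
  first_of_pair <- alive_pool[seq_len(n_extra)]
  second_of_pair <- alive_pool[n_extra + seq_len(n_extra)]
  subject_of <- integer(n)
  singles <- setdiff(seq_len(n), c(first_of_pair, second_of_pair))
  subject_ids <- 10000L + seq_len(config$n_patients)
  subject_of[singles] <- subject_ids[seq_along(singles)]
  if (n_extra > 0) {
    pair_ids <- subject_ids[length(singles) + seq_len(n_extra)]
    subject_of[first_of_pair] <- pair_ids
    subject_of[second_of_pair] <- pair_ids
  }

  ## ---- times in the shifted 2100-2200 window -------------------------
  window_start <- as.POSIXct("2101-01-01", tz = "UTC")
  span_days <- 35400                         # keeps pair timelines < 2200
  admit_time <- window_start + stats::runif(n, 0, span_days) * 86400
  if (n_extra > 0) {
    gap <- stats::rgamma(n_extra, shape = 1.5, scale = 40)
    admit_time[second_of_pair] <- admit_time[first_of_pair] +
      (hosp_los[first_of_pair] + gap + 1) * 86400
  }
  # whole-second timestamps so CSV round-trips preserve every interval
  admit_time <- round(admit_time, "secs")
  in_time <- round(admit_time + delay * 86400, "secs")
  out_time <- round(in_time + icu_los * 86400, "secs")
  discharge_time <- round(out_time + ward_tail * 86400, "secs")
  icu_los <- as.numeric(difftime(out_time, in_time, units = "days"))

  ## ---- patients table -------------------------------------------------
  pat_subject <- subject_ids
  # ages: truncated normal, adults only
  age <- stats::rnorm(config$n_patients, config$mean_age_overall, config$sd_age)
  while (any(age < 18))
    age[age < 18] <- stats::rnorm(sum(age < 18), config$mean_age_overall,
                                  config$sd_age)
  n_men <- lr_count(config$pct_men / 100, config$n_patients)
  sex <- rep("F", config$n_patients)
  sex[sample.int(config$n_patients, n_men)] <- "M"
  subj_dead <- tapply(dead, subject_of, any)
  pat_dead <- as.logical(subj_dead[as.character(pat_subject)])
  pat_dead[is.na(pat_dead)] <- FALSE

  patients <- data.frame(subject_id = pat_subject, sex = sex,
                         age = round(age, 1), dead_flag = pat_dead)

  ## ---- admissions / icustays ------------------------------------------
  hadm_id <- 100000L + seq_len(n)
  icustay_id <- 200000L + seq_len(n)
  admissions <- data.frame(
    subject_id = subject_of, hadm_id = hadm_id,
    admission_type = admission_type, admit_time = admit_time,
    discharge_time = discharge_time, diagnosis = diagnosis,
    admission_location = admission_location,
    discharge_location = discharge_location,
    hospital_expire_flag = as.integer(dead)
  )
  ward_pref <- match(diagnosis, dx_names)
  ward_id <- ward_pref
  reroute <- stats::runif(n) < 0.15
  if (length(dx_names) > 1) {
    ward_id[reroute] <- vapply(ward_pref[reroute], function(wq)
      sample(setdiff(seq_along(dx_names), wq), 1L), 1L)
  }
  icustays <- data.frame(
    hadm_id = hadm_id, icustay_id = icustay_id,
    in_time = in_time, out_time = out_time, los = icu_los,
    ward_id = as.integer(ward_id),
    sched_ward_transfer_hour = sched_out_hour
  )

  ## ---- prescriptions ---------------------------------------------------
  if (nrow(drows) > 0 && length(unlist(exposure)) > 0) {
    adm_idx <- unlist(exposure)
    cls <- rep(drows$class, vapply(exposure, length, 1L))
    drug <- vapply(cls, function(cl) {
      ex <- DRUG_EXAMPLES[[cl]]
      if (is.null(ex)) cl else sample(ex, 1L)
    }, "")
    start_frac <- stats::runif(length(adm_idx), 0, 0.3)
    sdate <- round(admit_time[adm_idx] +
                     start_frac * hosp_los[adm_idx] * 86400, "secs")
    edate <- round(sdate + stats::runif(length(adm_idx), 0.3, 0.9) *
      (hosp_los[adm_idx] * (1 - start_frac)) * 86400, "secs")
    edate <- pmin(edate, discharge_time[adm_idx])
    prescriptions <- data.frame(
      hadm_id = hadm_id[adm_idx], drug = unname(drug), drug_class = cls,
      start_date = sdate, end_date = edate,
      prod_strength = sample(PROD_STRENGTHS, length(adm_idx), replace = TRUE),
      frequency = sample(FREQUENCIES, length(adm_idx), replace = TRUE)
    )
    prescriptions <- prescriptions[order(prescriptions$hadm_id,
                                         prescriptions$drug_class), ]
    rownames(prescriptions) <- NULL
  } else {
    prescriptions <- empty_bundle(config)$prescriptions
  }

  ## ---- chart events: 3 timestamps x 4 items per stay -------------------
  n_ts <- 3L
  stay_rep <- rep(seq_len(n), each = n_ts)
  ts <- round(in_time[stay_rep] +
    stats::runif(n * n_ts, 0.05, 0.95) * icu_los[stay_rep] * 86400, "secs")
  vm <- config$vitals_mean
  hr <- round(stats::rnorm(n * n_ts, vm[["heart_rate"]], 12), 1)
  rr <- round(stats::rnorm(n * n_ts, vm[["resp_rate"]], 4), 1)
  bp <- round(stats::rnorm(n * n_ts, vm[["nibp"]], 15), 1)
  chartevents <- data.frame(
    icustay_id = rep(icustay_id[stay_rep], 4L),
    item = rep(CHART_ITEMS, each = n * n_ts),
    time = rep(ts, 4L),
    value = c(hr, rr, bp, bp),   # ibp mirrors nibp (continuous channel)
    missing_flag = FALSE
  )
  chartevents <- chartevents[order(chartevents$icustay_id, chartevents$time,
                                   match(chartevents$item, CHART_ITEMS)), ]
  rownames(chartevents) <- NULL

  structure(list(patients = patients, admissions = admissions,
                 icustays = icustays, prescriptions = prescriptions,
                 chartevents = chartevents),
            class = "ehr_bundle", config = config, seed = seed)
}

#' @export
print.ehr_bundle <- function(x, ...) {
  cat("<ehr_bundle>\n")
  for (nm in names(x)) cat(sprintf("  %-14s %6d rows\n", nm, nrow(x[[nm]])))
  invisible(x)
}

#' Flag a fraction of non-invasive blood-pressure readings as missing
#'
#' Emulates the lower recording frequency of non-invasive blood pressure:
#' a largest-remainder-exact fraction of `nibp` chart rows is flagged
#' missing (value set to `NA`) while the paired invasive channel stays
#' observed. The withheld value is kept in a `true_value` column so
#' imputation can be scored against ground truth.
#'
#' @param bundle An `ehr_bundle`.
#' @param nibp_missing_rate Fraction in [0, 1] of nibp rows to withhold.
#' @param seed Integer seed for the row selection.
#' @return The bundle with its `chartevents` table amended.
#' @export
inject_missingness <- function(bundle, nibp_missing_rate, seed = 1L) {
  stopifnot(inherits(bundle, "ehr_bundle"))
  if (nibp_missing_rate < 0 || nibp_missing_rate > 1)
    stop("nibp_missing_rate must lie in [0, 1]", call. = FALSE)
  ce <- bundle$chartevents
  if (!"true_value" %in% names(ce)) ce$true_value <- NA_real_
  nibp_rows <- which(ce$item == "nibp" & !ce$missing_flag)
  n_flag <- lr_count(nibp_missing_rate, length(nibp_rows))
  if (n_flag > 0) {
    set.seed(seed)
    hit <- sample(nibp_rows, n_flag)
    ce$true_value[hit] <- ce$value[hit]
    ce$value[hit] <- NA_real_
    ce$missing_flag[hit] <- TRUE
  }
  bundle$chartevents <- ce
  bundle
}
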