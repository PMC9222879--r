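#' Cohort configuration
#'
#' A `cohort_config` captures the printed baseline characteristics of the
#' cardiovascular ICU cohort the generator emulates: exact integer marginals
#' (admission routes, ICU diagnosis groups, deaths by diagnosis), drug-class
#' exposure shares, and the continuous summaries (mean age, sex share, mean
#' hospital length of stay overall / dead / alive).
#'
#' @param n_admissions Total hospital admissions.
#' @param n_patients Distinct subjects (readmissions allowed, so
#'   `n_patients <= n_admissions`).
#' @param admission_type_counts Named integer vector over
#'   `c("EMERGENCY","ELECTIVE","URGENT")`, summing to `n_admissions`.
#' @param diagnosis_counts Named integer vector over the three diagnosis
#'   groups, summing to `n_admissions`.
#' @param dead_by_diagnosis Named integer vector, deaths at discharge per
#'   diagnosis group; bounded by `diagnosis_counts`.
#' @param dead_by_admission_type Optional named integer vector of deaths per
#'   admission route (must sum to `sum(dead_by_diagnosis)`); if `NULL`,
#'   deaths are apportioned across routes by largest remainder.
#' @param drug_class_rows Data frame with columns `class`, `pct_overall`
#'   (share of admissions exposed, percent) and `pct_dead` (share of the
#'   exposed flagged dead at discharge, percent).
#' @param mean_age_overall Mean age in years (cohort is adults-only; ages
#'   are truncated at 18).
#' @param sd_age Age standard deviation in years.
#' @param pct_men Percent of subjects that are men.
#' @param mean_los_days Named numeric `c(overall=, dead=, alive=)`, mean
#'   hospital length of stay in days. The overall and dead means steer the
#'   generator; the alive mean is implied by the other two.
#' @param vitals_mean Named numeric means for `heart_rate` (bpm),
#'   `resp_rate` (cpm) and `nibp` (mmHg).
#' @param signal_noise_sd Gaussian noise (days) added to the planted
#'   discharge-readiness signal.
#' @param seed Default integer seed for generation.
#' @return An object of class `cohort_config`.
#' @seealso [default_config()], [generate_cohort()]
#' @export
cohort_config <- function(n_admissions,
                          n_patients,
                          admission_type_counts,
                          diagnosis_counts,
                          dead_by_diagnosis,
                          dead_by_admission_type = NULL,
                          drug_class_rows = empty_drug_rows(),
                          mean_age_overall = 65,
                          sd_age = 12,
                          pct_men = 53,
                          mean_los_days = c(overall = 2.9, dead = 3.1, alive = 2.7),
                          vitals_mean = c(heart_rate = 80, resp_rate = 21, nibp = 122),
                          signal_noise_sd = 0.25,
                          seed = 20120101L) {
  cfg <- structure(
    list(
      n_admissions = as.integer(n_admissions),
      n_patients = as.integer(n_patients),
      admission_type_counts = vapply(admission_type_counts, as.integer, 1L),
      diagnosis_counts = vapply(diagnosis_counts, as.integer, 1L),
      dead_by_diagnosis = vapply(dead_by_diagnosis, as.integer, 1L),
      dead_by_admission_type = if (is.null(dead_by_admission_type)) NULL
        else vapply(dead_by_admission_type, as.integer, 1L),
      drug_class_rows = drug_class_rows,
      mean_age_overall = mean_age_overall,
      sd_age = sd_age,
      pct_men = pct_men,
      mean_los_days = mean_los_days,
      vitals_mean = vitals_mean,
      signal_noise_sd = signal_noise_sd,
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
  validate_config(cfg)
  cfg
}

empty_drug_rows <- function() {
  data.frame(class = character(0), pct_overall = numeric(0),
             pct_dead = numeric(0), stringsAsFactors = FALSE)
}

#' Validate a cohort configuration
#'
#' Checks the structural invariants: marginals sum to the admission total,
#' deaths never exceed their diagnosis group, shares lie in [0, 100], and
#' the patient count does not exceed the admission count.
#'
#' @param config A [cohort_config()].
#' @return `config`, invisibly; stops with a diagnostic on violation.
#' @export
validate_config <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  if (config$n_admissions < 0 || config$n_patients < 0)
    stop("negative counts in cohort config", call. = FALSE)
  if (config$n_patients > config$n_admissions)
    stop("n_patients (", config$n_patients, ") exceeds n_admissions (",
         config$n_admissions, ")", call. = FALSE)
  if (sum(config$admission_type_counts) != config$n_admissions)
    stop("admission_type_counts sum to ", sum(config$admission_type_counts),
         ", expected n_admissions = ", config$n_admissions, call. = FALSE)
  if (sum(config$diagnosis_counts) != config$n_admissions)
    stop("diagnosis_counts sum to ", sum(config$diagnosis_counts),
         ", expected n_admissions = ", config$n_admissions, call. = FALSE)
  if (!all(names(config$dead_by_diagnosis) %in% names(config$diagnosis_counts)))
    stop("dead_by_diagnosis names must match diagnosis_counts", call. = FALSE)
  bad <- config$dead_by_diagnosis >
    config$diagnosis_counts[names(config$dead_by_diagnosis)]
  if (any(bad) || any(config$dead_by_diagnosis < 0))
    stop("dead counts exceed diagnosis counts for: ",
         paste(names(config$dead_by_diagnosis)[bad], collapse = ", "),
         call. = FALSE)
  if (!is.null(config$dead_by_admission_type)) {
    if (sum(config$dead_by_admission_type) != sum(config$dead_by_diagnosis))
      stop("dead_by_admission_type must sum to total deaths (",
           sum(config$dead_by_diagnosis), ")", call. = FALSE)
    if (any(config$dead_by_admission_type >
            config$admission_type_counts[names(config$dead_by_admission_type)]))
      stop("dead_by_admission_type exceeds admission_type_counts", call. = FALSE)
  }
  d <- config$drug_class_rows
  if (nrow(d) && (any(d$pct_overall < 0 | d$pct_overall > 100) ||
                  any(d$pct_dead < 0 | d$pct_dead > 100)))
    stop("drug-class shares must lie in [0, 100]", call. = FALSE)
  # readmission structure: each extra admission needs a distinct alive subject
  n_extra <- config$n_admissions - config$n_patients
  n_alive <- config$n_admissions - sum(config$dead_by_diagnosis)
  if (config$n_admissions > 0 && 2L * n_extra > n_alive)
    stop("too many readmissions for the number of alive admissions",
         call. = FALSE)
  invisible(config)
}

#' Default cohort configuration (baseline table of the study cohort)
#'
#' The configuration transcribed from the published baseline table:
#' 4402 admissions over 4226 patients; 2804 emergency, 1466 elective and
#' 132 urgent admissions; 2808 coronary artery disease, 1315 congestive
#' heart failure and 279 acute coronary syndrome diagnoses with 54/175/22
#' deaths at discharge; seventeen prescription drug classes with their
#' exposure and dead-at-discharge shares; mean age 65 years, 53% men, and a
#' 2.9-day mean hospital stay (3.1 days among dead-at-discharge).
#'
#' @return A [cohort_config()].
#' @examples
#' cfg <- default_config()
#' cfg$admission_type_counts[["EMERGENCY"]]
#' sum(cfg$diagnosis_counts)
#' @export
default_config <- function() {
  drug_rows <- data.frame(
    class = c("Cholesterol lowering medications", "ACE inhibitors",
              "Bronchodilators", "Diuretics", "Insulins", "Anticoagulants",
              "Electrolytes", "Beta blockers", "Antiplatelet agents and DAPT",
              "Anti-histamines", "Quinolone antibiotics", "Nitrates",
              "Peptides", "Glucose elevating agents", "Antidysrhythmics",
              "Calcium channel blockers", "Sulfonic acid"),
    pct_overall = c(12.83, 14.62, 10.66, 9.1, 7.85, 7.42, 13.22, 7.2, 3.46,
                    3.44, 3.2, 2.63, 1.36, 1.63, 0.89, 0.35, 0.15),
    pct_dead = c(0.14, 0.38, 0.47, 1, 1.04, 0.8, 0.66, 1.78, 3.58, 0.53,
                 1.42, 1.21, 1.01, 5.88, 4.6, 3.95, 6.06),
    stringsAsFactors = FALSE
  )
  cohort_config(
    n_admissions = 4402L,
    n_patients = 4226L,
    admission_type_counts = c(EMERGENCY = 2804L, ELECTIVE = 1466L, URGENT = 132L),
    diagnosis_counts = c(
      "CORONARY ARTERY DISEASE" = 2808L,
      "CONGESTIVE HEART FAILURE" = 1315L,
      "ACUTE CORONARY SYNDROME" = 279L
    ),
    dead_by_diagnosis = c(
      "CORONARY ARTERY DISEASE" = 54L,
      "CONGESTIVE HEART FAILURE" = 175L,
      "ACUTE CORONARY SYNDROME" = 22L
    ),
    dead_by_admission_type = c(EMERGENCY = 226L, ELECTIVE = 14L, URGENT = 11L),
    drug_class_rows = drug_rows,
    mean_age_overall = 65,
    pct_men = 53,
    mean_los_days = c(overall = 2.9, dead = 3.1, alive = 2.7),
    seed = 20120101L
  )
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat("  admissions:", x$n_admissions, " patients:", x$n_patients, "\n")
  cat("  admission types:",
      paste(names(x$admission_type_counts), x$admission_type_counts,
            sep = "=", collapse = ", "), "\n")
  cat("  diagnoses:",
      paste(names(x$diagnosis_counts), x$diagnosis_counts,
            sep = "=", collapse = ", "), "\n")
  cat("  deaths:", sum(x$dead_by_diagnosis),
      " drug classes:", nrow(x$drug_class_rows), "\n")
  cat("  mean age:", x$mean_age_overall, "y, mean LOS:",
      x$mean_los_days[["overall"]], "d, seed:", x$seed, "\n")
  invisible(x)
}
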