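# small feasible cohort configuration for fast tests
small_config <- function(n_adm = 60L, n_pat = 56L, seed = 42L) {
  cohort_config(
    n_admissions = n_adm,
    n_patients = n_pat,
    admission_type_counts = c(EMERGENCY = n_adm - 20L, ELECTIVE = 15L,
                              URGENT = 5L),
    diagnosis_counts = c("CORONARY ARTERY DISEASE" = n_adm - 25L,
                         "CONGESTIVE HEART FAILURE" = 18L,
                         "ACUTE CORONARY SYNDROME" = 7L),
    dead_by_diagnosis = c("CORONARY ARTERY DISEASE" = 2L,
                          "CONGESTIVE HEART FAILURE" = 4L,
                          "ACUTE CORONARY SYNDROME" = 1L),
    drug_class_rows = data.frame(
      class = c("Diuretics", "Beta blockers"),
      pct_overall = c(20, 10), pct_dead = c(10, 0)),
    seed = seed
  )
}

# random feasible integer-marginal configuration (for round-trip properties)
random_config <- function(seed) {
  set.seed(seed)
  n <- sample(30:120, 1)
  types <- as.integer(largest_remainder(runif(3, 0.1, 1), n))
  dxs <- as.integer(largest_remainder(runif(3, 0.1, 1), n))
  dead <- vapply(dxs, function(k) sample(0:min(k, max(0, k %/% 4)), 1), 1L)
  n_alive <- n - sum(dead)
  n_pat <- n - sample(0:max(0, min(5, n_alive %/% 2)), 1)
  cohort_config(
    n_admissions = n, n_patients = n_pat,
    admission_type_counts = stats::setNames(types,
      c("EMERGENCY", "ELECTIVE", "URGENT")),
    diagnosis_counts = stats::setNames(dxs,
      c("CORONARY ARTERY DISEASE", "CONGESTIVE HEART FAILURE",
        "ACUTE CORONARY SYNDROME")),
    dead_by_diagnosis = stats::setNames(dead,
      c("CORONARY ARTERY DISEASE", "CONGESTIVE HEART FAILURE",
        "ACUTE CORONARY SYNDROME")),
    seed = seed
  )
}

# synthetic encoded feature table with a known additive signal
synth_feature_table <- function(n, noise_sd = 0.2, seed = 1) {
  set.seed(seed)
  tab <- data.frame(
    a = runif(n, 0, 5),
    b = sample(0:3, n, replace = TRUE),
    c = rnorm(n)
  )
  tab$target_days <- pmin(pmax(1 + 0.8 * tab$a + 0.5 * tab$b +
                                 rnorm(n, 0, noise_sd), 0), 7)
  tab
}

# a random flow state with a hand-built roster (for rate oracles)
random_flow_state <- function(system, seed) {
  set.seed(seed)
  st <- flow_state(system)
  counts <- vapply(seq_len(system$M), function(q)
    sample(0:system$beds[q], 1), 1L)
  rows <- list()
  pid <- 1L
  for (q in seq_len(system$M)) {
    if (counts[q] == 0) next
    rows[[q]] <- data.frame(
      pid = pid + seq_len(counts[q]) - 1L, ward = q,
      pathology = sample(seq_len(system$K), counts[q], replace = TRUE),
      route = "EMERGENCY", entered_epoch = 0L, clock = 0L)
    pid <- pid + counts[q]
  }
  st$roster <- do.call(rbind, rows)
  if (is.null(st$roster)) st$roster <- flow_state(system)$roster
  st$arrivals_total <- nrow(st$roster)
  st
}
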