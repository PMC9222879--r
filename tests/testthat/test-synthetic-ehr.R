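test_that("default configuration carries the printed baseline marginals", {
  cfg <- default_config()
  expect_equal(cfg$admission_type_counts[["EMERGENCY"]], 2804L)
  expect_equal(sum(cfg$diagnosis_counts), 4402L)
  expect_equal(cfg$dead_by_diagnosis[["CONGESTIVE HEART FAILURE"]], 175L)
  expect_equal(cfg$n_patients, 4226L)
  expect_equal(sum(cfg$admission_type_counts), cfg$n_admissions)
  expect_equal(sum(cfg$dead_by_admission_type), sum(cfg$dead_by_diagnosis))
})

test_that("infeasible configurations are rejected with a diagnostic", {
  expect_error(small_config(n_pat = 70L), "n_patients")
  cfg <- small_config()
  cfg$dead_by_diagnosis[["ACUTE CORONARY SYNDROME"]] <- 100L
  expect_error(validate_config(cfg), "exceed")
  cfg2 <- small_config()
  cfg2$admission_type_counts[["URGENT"]] <- 99L
  expect_error(validate_config(cfg2), "admission_type_counts")
})

test_that("an empty configuration yields empty, valid tables", {
  cfg <- small_config()
  cfg$n_admissions <- 0L; cfg$n_patients <- 0L
  cfg$admission_type_counts[] <- 0L
  cfg$diagnosis_counts[] <- 0L
  cfg$dead_by_diagnosis[] <- 0L
  cfg$dead_by_admission_type <- NULL
  b <- generate_cohort(cfg)
  expect_s3_class(b, "ehr_bundle")
  expect_true(all(vapply(b, nrow, 1L) == 0L))
  expect_equal(nrow(validate_bundle(b)), 0L)
  s <- cohort_summary(b)
  expect_equal(s$n_admissions, 0L)
  expect_equal(s$n_patients, 0L)
})

test_that("generation is deterministic given (config, seed)", {
  cfg <- small_config()
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
  b3 <- generate_cohort(cfg, seed = 99L)
  expect_false(identical(generate_cohort(cfg)$admissions$admit_time,
                         b3$admissions$admit_time))
})

test_that("summary round-trips every integer marginal of feasible configs", {
  for (seed in c(11L, 23L, 37L)) {
    cfg <- random_config(seed)
    b <- generate_cohort(cfg)
    s <- cohort_summary(b)
    expect_equal(s$n_admissions, cfg$n_admissions)
    expect_equal(s$n_patients, cfg$n_patients)
    expect_equal(s$admission_type_counts[names(cfg$admission_type_counts)],
                 cfg$admission_type_counts)
    expect_equal(s$diagnosis_counts[names(cfg$diagnosis_counts)],
                 cfg$diagnosis_counts)
    got_dead <- s$dead_by_diagnosis[names(cfg$dead_by_diagnosis)]
    got_dead[is.na(got_dead)] <- 0L
    names(got_dead) <- names(cfg$dead_by_diagnosis)
    expect_equal(got_dead, cfg$dead_by_diagnosis)
    expect_equal(nrow(validate_bundle(b)), 0L)
  }
})

test_that("readmitted subjects have coherent two-admission timelines", {
  cfg <- small_config(n_adm = 60L, n_pat = 54L)
  b <- generate_cohort(cfg)
  tab <- table(b$admissions$subject_id)
  expect_equal(sum(tab == 2L), 6L)
  expect_equal(sum(tab == 1L), 48L)
  for (sid in names(tab)[tab == 2L]) {
    rows <- b$admissions[b$admissions$subject_id == as.integer(sid), ]
    rows <- rows[order(rows$admit_time), ]
    expect_true(rows$admit_time[2] > rows$discharge_time[1])
    # no readmission after a death
    expect_equal(rows$hospital_expire_flag[1], 0L)
  }
})

test_that("drug-class shares recompute to the configured percentages", {
  b <- generate_cohort(small_config(n_adm = 100L, n_pat = 96L))
  s <- cohort_summary(b)
  dr <- s$drug_class_rows
  expect_equal(dr$pct_overall[dr$class == "Diuretics"], 20)
  expect_equal(dr$pct_overall[dr$class == "Beta blockers"], 10)
  expect_equal(dr$pct_dead[dr$class == "Diuretics"], 10)
  expect_equal(dr$pct_dead[dr$class == "Beta blockers"], 0)
})

test_that("dates live in the shifted 2100-2200 window and intervals hold", {
  b <- generate_cohort(small_config())
  expect_true(all(b$admissions$admit_time >=
                    as.POSIXct("2100-01-01", tz = "UTC")))
  expect_true(all(b$admissions$discharge_time <=
                    as.POSIXct("2200-12-31", tz = "UTC")))
  expect_true(all(b$admissions$admit_time < b$admissions$discharge_time))
  expect_true(all(b$icustays$in_time < b$icustays$out_time))
  expect_equal(b$icustays$los,
               as.numeric(difftime(b$icustays$out_time, b$icustays$in_time,
                                   units = "days")))
})

test_that("missingness injection flags an exact fraction of nibp rows", {
  b <- generate_cohort(small_config())
  n_nibp <- sum(b$chartevents$item == "nibp")

  b0 <- inject_missingness(b, 0, seed = 5)
  expect_equal(sum(b0$chartevents$missing_flag), 0L)
  expect_equal(b0$chartevents$value, b$chartevents$value)

  b1 <- inject_missingness(b, 1, seed = 5)
  ce1 <- b1$chartevents
  expect_equal(sum(ce1$item == "nibp" & ce1$missing_flag), n_nibp)
  expect_true(all(!ce1$missing_flag[ce1$item == "ibp"]))

  b3 <- inject_missingness(b, 0.3, seed = 5)
  ce3 <- b3$chartevents
  expect_equal(sum(ce3$missing_flag),
               largest_remainder(c(0.3, 0.7), n_nibp)[1])
  # ground truth retained for every withheld value
  expect_true(all(!is.na(ce3$true_value[ce3$missing_flag])))
  expect_identical(inject_missingness(b, 0.3, seed = 5), b3)

  expect_error(inject_missingness(b, 1.2), "\\[0, 1\\]")
})
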