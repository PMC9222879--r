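test_that("occupancy is patients over beds, matching a roster enumeration", {
  sys <- ward_system(beds = c(2, 3))
  st <- flow_state(sys)
  st$roster <- data.frame(pid = 1L, ward = 1L, pathology = 1L,
                          route = "EMERGENCY", entered_epoch = 0L,
                          clock = 0L)
  U <- occupancy(st, sys)
  expect_equal(U[1, 1], 0.5)
  expect_equal(sum(U) - U[1, 1], 0)

  expect_equal(occupancy(flow_state(sys), sys),
               matrix(0, nrow = 2, ncol = 2))

  # brute-force oracle: count the roster patient by patient
  for (seed in 1:5) {
    sys3 <- ward_system(beds = c(4, 6, 3))
    st3 <- random_flow_state(sys3, seed)
    U3 <- occupancy(st3, sys3)
    for (q in 1:3) for (k in 1:3) {
      cnt <- 0
      for (i in seq_len(nrow(st3$roster)))
        if (st3$roster$ward[i] == q && st3$roster$pathology[i] == k)
          cnt <- cnt + 1
      expect_equal(U3[q, k], cnt / sys3$beds[q])
    }
  }
})

test_that("zero-bed wards get occupancy zero with a warning", {
  sys <- ward_system(beds = c(0, 2))
  expect_warning(U <- occupancy(flow_state(sys), sys), "zero beds")
  expect_equal(U[1, ], c(0, 0))
})

test_that("alpha/beta match an independent loop-based re-summation", {
  for (seed in 1:100) {
    sys <- ward_system(beds = sample(1:6, 3, replace = TRUE))
    st <- random_flow_state(sys, seed)
    if (nrow(st$roster) == 0) {
      expect_error(flow_rates(st, sys), "empty-system")
      next
    }
    r <- flow_rates(st, sys)
    # oracle: re-sum the occupancy matrix and free beds with plain loops
    U <- suppressWarnings(occupancy(st, sys))
    sumU <- 0; for (q in 1:3) for (k in 1:3) sumU <- sumU + U[q, k]
    sumF <- 0; for (q in 1:3) sumF <- sumF +
      (sys$beds[q] - sum(st$roster$ward == q))
    D <- sumU + sumF
    for (k in 1:3) {
      alpha_k <- 0
      for (q in 1:3) if (sys$pathology_of_ward[q] == k)
        alpha_k <- alpha_k + U[q, k]
      expect_equal(r$alpha[k], alpha_k / D)
    }
    beta_raw <- (D - sumU - sumF) / D
    expect_equal(r$beta[1, 1], min(max(beta_raw, 0), 1))
    expect_true(all(r$alpha >= 0 & r$alpha <= 1))
    expect_true(all(r$beta >= 0 & r$beta <= 1))
  }
})

test_that("fully primary, saturated wards give alpha summing to 1, beta 0", {
  sys <- ward_system(beds = c(2, 3))
  st <- allocate(flow_state(sys),
                 data.frame(pathology = c(1, 2), route = "EMERGENCY",
                            n = c(2, 3)), sys)
  r <- flow_rates(st, sys)
  expect_equal(sum(r$alpha), 1)
  expect_equal(max(abs(r$beta)), 0)
  expect_error(flow_rates(flow_state(sys), sys), "empty-system")
})

test_that("allocation prefers the home ward, spills over, then queues", {
  sys <- ward_system(beds = c(4, 3, 5))
  # one arrival, preferred ward free
  st <- allocate(flow_state(sys),
                 data.frame(pathology = 2, route = "ELECTIVE", n = 1), sys)
  expect_equal(st$roster$ward, 2L)
  expect_equal(nrow(st$overflow), 0L)

  # saturated system: occupancies unchanged, overflow grows by one
  full <- allocate(flow_state(sys),
                   data.frame(pathology = c(1, 2, 3), route = "EMERGENCY",
                              n = c(12, 0, 0)), sys)
  occ_before <- rowSums(icuflow:::occupied_counts(full, sys))
  full2 <- allocate(full, data.frame(pathology = 1, route = "EMERGENCY",
                                     n = 1), sys)
  expect_equal(rowSums(icuflow:::occupied_counts(full2, sys)), occ_before)
  expect_equal(nrow(full2$overflow), nrow(full$overflow) + 1L)

  # hand-simulated: 10 arrivals, preferred ward 4 free, one alternative 3
  sys2 <- ward_system(beds = c(4, 3), n_pathologies = 2)
  st2 <- allocate(flow_state(sys2), data.frame(pathology = 2, route = "URGENT",
                                               n = 3), sys2)  # fill ward 2
  st2 <- allocate(st2, data.frame(pathology = 1, route = "EMERGENCY", n = 10),
                  sys2)
  expect_equal(sum(st2$roster$ward == 1 & st2$roster$pathology == 1), 4L)
  expect_equal(nrow(st2$overflow), 6L)

  sys3 <- ward_system(beds = c(4, 3))
  st3 <- allocate(flow_state(sys3),
                  data.frame(pathology = 1, route = "EMERGENCY", n = 10), sys3)
  expect_equal(sum(st3$roster$ward == 1), 4L)   # primary
  expect_equal(sum(st3$roster$ward == 2), 3L)   # secondary
  expect_equal(nrow(st3$overflow), 3L)          # queued
  expect_true(conservation_holds(st3))

  expect_error(allocate(flow_state(sys3),
                        data.frame(pathology = 1, route = "EMERGENCY",
                                   n = -1), sys3), "negative")
})

test_that("overflow retries FIFO before new arrivals", {
  sys <- ward_system(beds = 1, n_pathologies = 1)
  st <- allocate(flow_state(sys),
                 data.frame(pathology = 1, route = "EMERGENCY", n = 3), sys)
  expect_equal(nrow(st$overflow), 2L)
  st <- inspect_and_discharge(st, sys, 1, seed = 1)   # frees the bed
  st <- allocate(st, data.frame(pathology = 1, route = "ELECTIVE", n = 1),
                 sys)
  # the bed goes to the queued (emergency) patient, not the new elective
  expect_equal(st$roster$route, "EMERGENCY")
  expect_equal(st$overflow$route, c("EMERGENCY", "ELECTIVE"))
  expect_equal(st$overflow$arrival_epoch, c(0L, 1L))
})

test_that("inspection discharges follow the Bernoulli dynamics", {
  sys <- ward_system(beds = c(10, 10))
  st <- allocate(flow_state(sys),
                 data.frame(pathology = c(1, 2), route = "EMERGENCY",
                            n = c(10, 10)), sys)
  st0 <- inspect_and_discharge(st, sys, 0, seed = 1)
  expect_equal(sum(st0$xi_last), 0L)
  expect_equal(nrow(st0$roster), 20L)
  expect_equal(st0$gamma, 0L)

  st1 <- inspect_and_discharge(st, sys, 1, seed = 1)
  expect_equal(sum(st1$xi_last), 20L)
  expect_equal(nrow(st1$roster), 0L)
  expect_equal(st1$gamma, 20L)

  expect_error(inspect_and_discharge(st, sys, 1.5), "\\[0, 1\\]")

  # binomial closed form: mean discharges per inspection ~ n*p
  sysb <- ward_system(beds = 100, n_pathologies = 1)
  stb <- allocate(flow_state(sysb),
                  data.frame(pathology = 1, route = "EMERGENCY", n = 100),
                  sysb)
  set.seed(7)
  reps <- 2000
  xi <- vapply(seq_len(reps), function(i)
    sum(inspect_and_discharge(stb, sysb, 0.3)$xi_last), 1L)
  se <- sqrt(100 * 0.3 * 0.7) / sqrt(reps)
  expect_lt(abs(mean(xi) - 30), 3 * se)
})

test_that("trajectories conserve patients and accumulate discharges", {
  sys <- ward_system(beds = c(6, 5, 4))
  # zero arrivals: nothing ever happens
  res0 <- run_flow(sys, data.frame(pathology = 1, route = "EMERGENCY", n = 0),
                   0.3, horizon = 20, seed = 1)
  expect_true(all(res0$epochs$gamma == 0))
  expect_true(all(res0$epochs$occupied == 0))

  arr <- data.frame(pathology = 1:3, route = "EMERGENCY", n = c(1, 1, 1))
  res <- run_flow(sys, arr, 0.35, horizon = 300, seed = 2)
  expect_true(all(res$epochs$conserved))
  expect_true(!is.unsorted(res$epochs$gamma))
  expect_true(all(res$wards$occupied <= res$wards$beds))
  # stable regime: arrivals below service capacity keep the queue bounded
  expect_lt(max(res$epochs$overflow), 60)
})

test_that("ample beds give a geometric sojourn with mean 1/p", {
  sys <- ward_system(beds = 4000, n_pathologies = 1)
  sched <- c(list(data.frame(pathology = 1, route = "EMERGENCY", n = 3000)),
             rep(list(data.frame(pathology = 1, route = "EMERGENCY", n = 0)),
                 149))
  res <- run_flow(sys, sched, 0.25, horizon = 150, seed = 5)
  soj <- res$state$discharge_ledger$sojourn
  expect_gt(length(soj), 2900)
  expect_lt(abs(mean(soj) - 4), 3 * sqrt((1 - 0.25) / 0.25^2) / sqrt(length(soj)))
})

test_that("discharge probability calibration inverts the mean stay", {
  expect_equal(discharge_prob_from_los(2, inspections_per_day = 2), 0.25)
  expect_equal(discharge_prob_from_los(0.1, 1), 1)
})
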