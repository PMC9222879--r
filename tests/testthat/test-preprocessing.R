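make_missing_bundle <- function(rate = 0.3, seed = 9L) {
  inject_missingness(generate_cohort(small_config()), rate, seed = seed)
}

test_that("invasive backfill recovers withheld nibp values exactly", {
  b <- make_missing_bundle(0.3)
  filled <- backfill_nibp(b, offset = 0)
  ce <- filled$chartevents
  withheld <- which(!is.na(ce$true_value))
  expect_gt(length(withheld), 0)
  expect_equal(ce$value[withheld], ce$true_value[withheld])
  expect_false(any(is.na(ce$value[ce$item == "nibp"])))

  # observed rows are untouched, offset shifts only the backfilled ones
  b0 <- generate_cohort(small_config())
  expect_identical(backfill_nibp(b0)$chartevents$value, b0$chartevents$value)
  off <- backfill_nibp(b, offset = 2)$chartevents
  expect_equal(off$value[withheld], off$true_value[withheld] + 2)
})

test_that("rows missing both channels fall through to median imputation", {
  b <- make_missing_bundle(0.5)
  ce <- b$chartevents
  # knock out the paired invasive reading for one withheld nibp row
  miss <- which(ce$item == "nibp" & ce$missing_flag)[1]
  pair <- which(ce$item == "ibp" & ce$icustay_id == ce$icustay_id[miss] &
                  ce$time == ce$time[miss])
  ce$value[pair] <- NA
  b$chartevents <- ce
  filled <- backfill_nibp(b)
  expect_true(is.na(filled$chartevents$value[miss]))
  feats <- build_features(b, impute = "median")
  expect_equal(sum(is.na(feats)), 0L)
})

test_that("median imputation matches a sort-based oracle", {
  tab <- data.frame(x = c(1, NA, 3))
  expect_equal(impute_median(tab, "x")$x, c(1, 2, 3))
  tab2 <- data.frame(x = c(2, 5, 9))
  expect_identical(impute_median(tab2, "x"), tab2)
  expect_error(impute_median(data.frame(x = c(NA_real_, NA_real_)), "x"),
               "all values missing")
  expect_error(impute_median(data.frame(x = letters[1:3]), "x"),
               "not numeric")

  set.seed(3)
  for (i in 1:5) {
    x <- rnorm(101)
    x[sample(101, 20)] <- NA
    got <- impute_median(data.frame(x = x), "x")$x
    obs <- sort(x[!is.na(x)])          # sort-based median oracle
    m <- length(obs)
    oracle <- if (m %% 2 == 1) obs[(m + 1) / 2]
              else (obs[m / 2] + obs[m / 2 + 1]) / 2
    expect_equal(unique(got[is.na(x)]), oracle)
    expect_equal(got[!is.na(x)], x[!is.na(x)])
  }
})

test_that("tree imputation recovers deterministic structure and beats the median", {
  set.seed(11)
  n <- 300
  tab <- data.frame(u = runif(n, 0, 10))
  tab$v <- tab$u                       # exact copy signal
  mask <- sample(n, 40)
  truth <- tab$v[mask]
  tab$v[mask] <- NA
  got <- impute_tree(tab, "v", seed = 2)
  expect_equal(sum(is.na(got$v)), 0L)
  expect_lt(max(abs(got$v[mask] - truth)), 0.35)  # leaf width on 10-unit range
  expect_equal(got$u, tab$u)

  # identity on a complete table
  full <- data.frame(a = rnorm(20), b = rnorm(20))
  expect_identical(impute_tree(full), full)

  # planted linear relation: tree imputation beats the median baseline
  set.seed(12)
  lin <- data.frame(x = runif(n, 0, 5))
  lin$y <- 2 * lin$x + rnorm(n, 0, 0.1)
  m2 <- sample(n, 30)
  truth2 <- lin$y[m2]
  lin$y[m2] <- NA
  tree_rmse <- sqrt(mean((impute_tree(lin, "y")$y[m2] - truth2)^2))
  med_rmse <- sqrt(mean((impute_median(lin, "y")$y[m2] - truth2)^2))
  expect_lt(tree_rmse, med_rmse)
})

test_that("ordinal encoding uses first-appearance codes and inverts exactly", {
  enc <- encode_categoricals(data.frame(loc = c("home", "snf", "home")))
  expect_equal(enc$table$loc, c(0L, 1L, 0L))
  expect_equal(enc$codebook$loc, c("home", "snf"))

  empty <- encode_categoricals(data.frame(loc = character(0)))
  expect_equal(nrow(empty$table), 0L)

  set.seed(4)
  for (i in 1:5) {
    tab <- data.frame(
      a = sample(c("x", "y", "zz"), 30, replace = TRUE),
      b = sample(LETTERS[1:5], 30, replace = TRUE),
      n = rnorm(30))
    enc <- encode_categoricals(tab)
    dec <- decode_categoricals(enc$table, enc$codebook)
    expect_equal(dec$a, tab$a)
    expect_equal(dec$b, tab$b)
    expect_equal(enc$table$n, tab$n)
  }

  # unseen level at transform time gets the reserved code
  cb <- encode_categoricals(data.frame(a = c("p", "q")))$codebook
  expect_warning(
    out <- encode_categoricals(data.frame(a = c("p", "r")), codebook = cb),
    "unseen")
  expect_equal(out$table$a, c(0L, -1L))
  expect_equal(decode_categoricals(out$table, cb)$a, c("p", NA))
})

test_that("the feature table is one row per stay with no missing cells", {
  b <- make_missing_bundle(0.4)
  feats <- build_features(b, impute = "tree")
  expect_equal(nrow(feats), nrow(b$icustays))
  expect_equal(anyDuplicated(feats$icustay_id), 0L)
  expect_equal(sum(is.na(feats)), 0L)
  expect_true(all(c("discharge_location", "diagnosis", "admission_location",
                    "drug", "los", "target_days") %in% names(feats)))
  # imputation never alters observed cells: spot-check the target and los
  feats2 <- build_features(b, impute = "median")
  expect_equal(feats2$target_days, feats$target_days)
  expect_equal(feats2$los, feats$los)
})

test_that("split-gain importance behaves at the edges", {
  set.seed(6)
  n <- 400
  tab <- data.frame(x1 = runif(n), x2 = runif(n), x3 = runif(n))
  tab$target_days <- ifelse(tab$x2 > 0.5, 4, 1)
  m <- fit_model(model_spec("gbm_light", params = list(nrounds = 10,
                                                       max_depth = 1),
                            early_stopping = FALSE, seed = 1), tab)
  imp <- feature_importance(m)
  expect_equal(imp$feature[1], "x2")
  expect_equal(imp$gain_pct[1], 100)
  expect_equal(imp$gain_pct[imp$feature != "x2"], c(0, 0))

  # permutation null: independent target spreads the gains thin
  tab$target_days <- sample(tab$target_days)
  m0 <- fit_model(model_spec("gbm_light", params = list(nrounds = 30),
                             early_stopping = FALSE, seed = 2), tab)
  imp0 <- feature_importance(m0)
  expect_lt(max(imp0$gain_share), 0.6)
  # stability: same seed, same ranking
  m0b <- fit_model(model_spec("gbm_light", params = list(nrounds = 30),
                              early_stopping = FALSE, seed = 2), tab)
  expect_equal(feature_importance(m0b), imp0)
})

test_that("the correlation screen drops one of each near-duplicate pair", {
  set.seed(14)
  tab <- data.frame(p = rnorm(50))
  tab$q <- tab$p + rnorm(50, 0, 0.01)   # |r| ~ 1
  tab$r <- rnorm(50)
  tab$target_days <- runif(50, 0, 7)
  out <- drop_correlated(tab)
  expect_equal(attr(out, "dropped"), "q")
  expect_true(all(c("p", "r", "target_days") %in% names(out)))
  # below-threshold table is untouched
  out2 <- drop_correlated(tab[, c("p", "r", "target_days")])
  expect_length(attr(out2, "dropped"), 0)
})
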