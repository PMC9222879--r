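test_that("evaluation metrics match a loop-based oracle", {
  ev <- evaluate_predictions(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ev$accuracy, 1)
  expect_equal(ev$residual_mean, 0)

  ev2 <- evaluate_predictions(c(3, 4, 5), c(1, 2, 3), tolerance_days = 1)
  expect_equal(ev2$accuracy, 0)
  expect_equal(ev2$residual_mean, 2)

  set.seed(8)
  pred <- runif(1000, 0, 7); truth <- runif(1000, 0, 7)
  ev3 <- evaluate_predictions(pred, truth)
  acc <- 0; ss <- 0
  for (i in seq_len(1000)) {
    if (abs(pred[i] - truth[i]) <= 1) acc <- acc + 1
    ss <- ss + (pred[i] - truth[i])^2
  }
  expect_equal(ev3$accuracy, acc / 1000)
  expect_equal(ev3$residual_mean, sqrt(ss / 1000))

  expect_error(evaluate_predictions(1:3, 1:2), "length mismatch")
  expect_error(evaluate_predictions(numeric(0), numeric(0)), "empty")
})

test_that("a constant target is fit exactly by every family", {
  tab <- synth_feature_table(80)
  tab$target_days <- 2.5
  for (fam in c("decision_tree", "gbm_light", "sgd_linear")) {
    m <- fit_model(model_spec(fam, params = if (fam == "gbm_light")
      list(nrounds = 20) else list(), early_stopping = FALSE, seed = 1), tab)
    ev <- evaluate_predictions(predict(m, tab), tab$target_days)
    expect_lt(ev$residual_mean, 0.05)
  }
})

test_that("SGD linear regression recovers a pure linear signal", {
  tab <- synth_feature_table(500, noise_sd = 0.1, seed = 2)
  m <- fit_model(model_spec("sgd_linear", seed = 3), tab)
  ev <- evaluate_predictions(predict(m, tab), tab$target_days)
  expect_lt(ev$residual_mean, 0.1 + 0.05)   # in-sample RM below noise sd + slack
  expect_true(m$fit$lr %in% c(1e-3, 1e-2, 1e-1))
  expect_true(m$fit$penalty %in% c("l2", "elasticnet"))
})

test_that("fitting refuses missing values and empty tables", {
  tab <- synth_feature_table(30)
  tab$a[3] <- NA
  expect_error(fit_model(model_spec("decision_tree"), tab), "missing values")
  expect_error(fit_model(model_spec("decision_tree"), tab[0, ]), "empty")
})

test_that("the AVG blender is exactly the mean of its bases", {
  tab <- synth_feature_table(200, seed = 5)
  te <- synth_feature_table(60, seed = 6)
  spec <- model_spec("blend_avg",
                     base_families = c("decision_tree", "sgd_linear"),
                     seed = 4)
  m <- fit_model(spec, tab)
  base_preds <- vapply(m$fit$bases, function(b) predict(b, te),
                       numeric(nrow(te)))
  expect_lt(max(abs(rowMeans(base_preds) - predict(m, te))), 1e-12)
  expect_error(model_spec("blend_avg", base_families = "decision_tree"),
               "at least two")
})

test_that("stacked blenders predict and stay within the horizon", {
  tab <- synth_feature_table(250, seed = 7)
  te <- synth_feature_table(80, seed = 8)
  for (fam in c("blend_glrm", "blend_enet")) {
    m <- fit_model(model_spec(fam,
                              base_families = c("decision_tree", "sgd_linear"),
                              seed = 5), tab)
    p <- predict(m, te)
    expect_true(all(is.finite(p)))
    expect_true(all(p >= 0 & p <= 7))
    ev <- evaluate_predictions(p, te$target_days)
    expect_lt(ev$residual_mean, 1)
  }
})

test_that("predictions are clipped, empty-safe and schema-checked", {
  tab <- synth_feature_table(120, seed = 9)
  tab$target_days <- tab$target_days * 3   # pushes raw predictions past 7
  m <- fit_model(model_spec("sgd_linear", seed = 1), tab)
  p <- predict(m, tab)
  expect_true(all(p >= 0 & p <= 7))
  expect_equal(predict(m, tab[0, ]), numeric(0))
  expect_error(predict(m, tab[, c("a", "target_days")]), "schema mismatch")

  # a leaf-pure tree replays its training targets exactly
  small <- data.frame(a = c(1, 2, 3, 4) * 1.0,
                      target_days = c(1, 1, 5, 5) * 1.0)
  small <- small[rep(1:4, each = 5), ]
  mt <- fit_model(model_spec("decision_tree", params = list(minbucket = 1,
                                                            minsplit = 2)),
                  small)
  expect_equal(predict(mt, small), small$target_days)
})

test_that("early stopping keeps the best checkpoint seen", {
  tab <- synth_feature_table(400, noise_sd = 0.5, seed = 10)
  m <- fit_model(model_spec("gbm_light", params = list(nrounds = 300),
                            seed = 2), tab)
  at <- attributes(m$fit)
  log <- at$evaluation_log
  best <- unname(at$early_stop$best_score)
  expect_equal(best, min(log$validation_rmse))
  expect_lte(best, log$validation_rmse[nrow(log)])
})

test_that("grid search equals brute-force enumeration with stated tie-breaks", {
  tr <- synth_feature_table(200, seed = 11)
  va <- synth_feature_table(100, seed = 12)

  single <- grid_search("decision_tree", list(maxdepth = 4), tr, va)
  expect_equal(single$spec$params$maxdepth, 4)

  grid <- list(nrounds = c(20, 60), max_depth = c(2, 4))
  gs <- grid_search("gbm_light", grid, tr, va, early_stopping = FALSE,
                    seed = 3)
  # brute force: refit every combination independently
  combos <- expand.grid(grid)
  rms <- vapply(seq_len(nrow(combos)), function(i) {
    m <- fit_model(model_spec("gbm_light",
                              params = as.list(combos[i, ]),
                              early_stopping = FALSE, seed = 3), tr)
    evaluate_predictions(predict(m, va), va$target_days)$residual_mean
  }, 0)
  best <- order(rms, combos$nrounds, combos$max_depth)[1]
  expect_equal(gs$spec$params$nrounds, combos$nrounds[best])
  expect_equal(gs$spec$params$max_depth, combos$max_depth[best])
  expect_equal(gs$results$residual_mean, rms)

  expect_error(grid_search("gbm_light", list(), tr, va), "empty grid")
})

test_that("grid search recovers the generating depth on noiseless data", {
  set.seed(13)
  n <- 400
  tab <- data.frame(x = runif(n))
  # two nested splits: needs depth 2, depth 1 underfits
  tab$target_days <- ifelse(tab$x < 0.5, ifelse(tab$x < 0.25, 1, 2),
                            ifelse(tab$x < 0.75, 4, 6))
  tr <- tab[1:300, ]; va <- tab[301:400, ]
  gs <- grid_search("decision_tree", list(maxdepth = c(1, 2)), tr, va)
  expect_equal(gs$spec$params$maxdepth, 2)
})
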