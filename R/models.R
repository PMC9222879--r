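MODEL_FAMILIES <- c("decision_tree", "gbm_extreme", "gbm_greedy", "gbm_light",
                    "sgd_linear", "blend_glrm", "blend_enet", "blend_avg")
BLEND_FAMILIES <- c("blend_glrm", "blend_enet", "blend_avg")

#' Specify a model from the zoo
#'
#' Eight regressor families: the baseline decision tree (max depth 10,
#' min leaf 4, min split 10, squared-error criterion), three
#' gradient-boosted variants with early stopping (2000 estimators,
#' learning rate 0.3, min leaf 2, min split 5; `gbm_extreme` uses the
#' regularized second-order objective, `gbm_greedy` exact greedy splits,
#' `gbm_light` histogram binning), an auto-tuned stochastic-gradient
#' linear regressor (learning-rate and penalty grid selected on a
#' validation slice), and three stacked blenders over base models: a
#' ridge-penalized linear meta-learner (`blend_glrm`), a single-hidden-
#' layer feed-forward meta-learner with 16 units (`blend_enet`), and the
#' unweighted mean (`blend_avg`).
#'
#' @param family One of `r paste(MODEL_FAMILIES, collapse=", ")`.
#' @param params Named list of hyperparameter overrides.
#' @param base_families For blenders: at least two base families to stack
#'   (default: tree, extreme and light boosters, SGD linear).
#' @param early_stopping Use a held-out 10% slice to stop boosting when it
#'   stops improving for 50 rounds.
#' @param horizon_days Predictions are clipped to [0, horizon_days]
#'   (discharges are predicted within a week).
#' @param seed Integer seed.
#' @return A `model_spec`.
#' @export
model_spec <- function(family, params = list(),
                       base_families = c("decision_tree", "gbm_extreme",
                                         "gbm_light", "sgd_linear"),
                       early_stopping = TRUE, horizon_days = 7, seed = 1L) {
  family <- match.arg(family, MODEL_FAMILIES)
  if (family %in% BLEND_FAMILIES && length(base_families) < 2)
    stop("blenders need at least two base families", call. = FALSE)
  defaults <- switch(family,
    decision_tree = list(maxdepth = 10, minbucket = 4, minsplit = 10),
    gbm_extreme = list(nrounds = 2000, eta = 0.3, min_child_weight = 2,
                       max_depth = 6, lambda = 1, tree_method = "exact"),
    gbm_greedy = list(nrounds = 2000, eta = 0.3, min_child_weight = 2,
                      max_depth = 6, lambda = 0, tree_method = "exact"),
    gbm_light = list(nrounds = 2000, eta = 0.3, min_child_weight = 2,
                     max_depth = 6, lambda = 1, tree_method = "hist"),
    sgd_linear = list(learning_rates = c(1e-3, 1e-2, 1e-1),
                      penalties = c("l2", "elasticnet"), lambda = 1e-4,
                      epochs = 40, batch = 32),
    list())
  params <- utils::modifyList(defaults, params)
  structure(list(family = family, params = params,
                 base_families = base_families,
                 early_stopping = isTRUE(early_stopping),
                 horizon_days = horizon_days, seed = as.integer(seed)),
            class = "model_spec")
}

feature_matrix <- function(table, features = NULL, target = "target_days") {
  drop <- c("icustay_id", target)
  if (is.null(features)) features <- setdiff(names(table), drop)
  chr <- features[vapply(table[features], function(x)
    is.character(x) || is.factor(x), TRUE)]
  if (length(chr) > 0)
    stop("categorical columns not encoded: ", paste(chr, collapse = ", "),
         " (run encode_categoricals first)", call. = FALSE)
  x <- as.matrix(table[, features, drop = FALSE])
  storage.mode(x) <- "double"
  x
}

check_train_table <- function(table, target) {
  if (nrow(table) == 0) stop("empty training table", call. = FALSE)
  if (!target %in% names(table)) stop("missing target column '", target, "'",
                                      call. = FALSE)
  if (anyNA(table)) stop("training table contains missing values; ",
                         "impute before fitting", call. = FALSE)
}

## ---- hand-rolled mini-batch SGD linear regression -----------------------

sgd_fit_once <- function(x, y, lr, penalty, lambda, epochs, batch, seed) {
  set.seed(seed)
  n <- nrow(x); p <- ncol(x)
  w <- rep(0, p); b <- mean(y)
  for (e in seq_len(epochs)) {
    idx <- sample.int(n)
    for (s in seq(1, n, by = batch)) {
      rows <- idx[s:min(s + batch - 1, n)]
      xb <- x[rows, , drop = FALSE]
      resid <- drop(xb %*% w) + b - y[rows]
      grad_w <- drop(crossprod(xb, resid)) / length(rows)
      pen <- switch(penalty,
                    l2 = lambda * w,
                    elasticnet = lambda * (0.5 * w + 0.5 * sign(w)))
      w <- w - lr * (grad_w + pen)
      b <- b - lr * mean(resid)
    }
    if (any(!is.finite(w))) {            # diverged at this learning rate
      w <- rep(NA_real_, p); break
    }
  }
  list(w = w, b = b)
}

fit_sgd_linear <- function(x, y, params, seed) {
  mu <- colMeans(x); sdv <- apply(x, 2, stats::sd); sdv[sdv == 0] <- 1
  xs <- sweep(sweep(x, 2, mu), 2, sdv, "/")
  set.seed(seed)
  n <- nrow(xs)
  val <- sample.int(n, max(1, floor(0.1 * n)))
  tr <- setdiff(seq_len(n), val)
  if (length(tr) == 0) tr <- val
  grid <- expand.grid(lr = params$learning_rates, penalty = params$penalties,
                      stringsAsFactors = FALSE)
  best <- NULL; best_rm <- Inf
  for (g in seq_len(nrow(grid))) {
    fit <- sgd_fit_once(xs[tr, , drop = FALSE], y[tr], grid$lr[g],
                        grid$penalty[g], params$lambda, params$epochs,
                        params$batch, seed + g)
    if (anyNA(fit$w)) next
    pred <- drop(xs[val, , drop = FALSE] %*% fit$w) + fit$b
    rm_val <- sqrt(mean((pred - y[val])^2))
    if (is.finite(rm_val) && rm_val < best_rm) {
      best_rm <- rm_val
      best <- c(fit, list(lr = grid$lr[g], penalty = grid$penalty[g]))
    }
  }
  if (is.null(best)) stop("SGD diverged for every grid point", call. = FALSE)
  # refit on all rows with the selected setting
  fit <- sgd_fit_once(xs, y, best$lr, best$penalty, params$lambda,
                      params$epochs, params$batch, seed)
  list(w = fit$w, b = fit$b, mu = mu, sd = sdv,
       lr = best$lr, penalty = best$penalty)
}

## ---- fitting ------------------------------------------------------------

fit_xgb <- function(x, y, params, early_stopping, seed) {
  set.seed(seed)
  n <- nrow(x)
  xgb_params <- list(objective = "reg:squarederror", eta = params$eta,
                     max_depth = params$max_depth,
                     min_child_weight = params$min_child_weight,
                     lambda = params$lambda,
                     tree_method = params$tree_method, nthread = 1)
  if (early_stopping && n >= 20) {
    val <- sample.int(n, max(2, floor(0.1 * n)))
    tr <- setdiff(seq_len(n), val)
    dtrain <- xgboost::xgb.DMatrix(x[tr, , drop = FALSE], label = y[tr])
    dval <- xgboost::xgb.DMatrix(x[val, , drop = FALSE], label = y[val])
    fit <- xgboost::xgb.train(xgb_params, dtrain, nrounds = params$nrounds,
                              evals = list(validation = dval),
                              early_stopping_rounds = 50, verbose = 0)
  } else {
    dtrain <- xgboost::xgb.DMatrix(x, label = y)
    fit <- xgboost::xgb.train(xgb_params, dtrain, nrounds = params$nrounds,
                              verbose = 0)
  }
  fit
}

#' Fit a model from the zoo
#'
#' Trains the specified regressor on an encoded, fully observed feature
#' table. Gradient-boosted families hold out a random 10% slice and stop
#' once that slice has not improved for 50 rounds, keeping the best
#' checkpoint. Blenders fit their base models on the full training table
#' and train the meta-learner on out-of-sample base predictions from an
#' internal 75/25 stacking split (the AVG blender needs no meta-learner).
#'
#' @param spec A [model_spec()].
#' @param train Feature table including the target column; no missing
#'   values; categoricals already encoded.
#' @param target Target column name (default `"target_days"`).
#' @return An `icuflow_model` (fit + feature names + spec).
#' @export
fit_model <- function(spec, train, target = "target_days") {
  stopifnot(inherits(spec, "model_spec"))
  check_train_table(train, target)
  features <- setdiff(names(train), c("icustay_id", target))
  x <- feature_matrix(train, features, target)
  y <- train[[target]]
  p <- spec$params

  fit <- switch(spec$family,
    decision_tree = rpart::rpart(
      stats::reformulate(features, response = target),
      data = train, method = "anova",
      control = rpart::rpart.control(maxdepth = p$maxdepth,
                                     minbucket = p$minbucket,
                                     minsplit = p$minsplit,
                                     cp = 1e-8, xval = 0)),
    gbm_extreme = ,
    gbm_greedy = ,
    gbm_light = fit_xgb(x, y, p, spec$early_stopping, spec$seed),
    sgd_linear = fit_sgd_linear(x, y, p, spec$seed),
    blend_glrm = ,
    blend_enet = ,
    blend_avg = fit_blender(spec, train, target, features)
  )
  structure(list(family = spec$family, fit = fit, features = features,
                 target = target, spec = spec),
            class = "icuflow_model")
}

fit_blender <- function(spec, train, target, features) {
  base_specs <- lapply(seq_along(spec$base_families), function(i) {
    fam <- spec$base_families[i]
    params <- if (grepl("^gbm_", fam) && !is.null(spec$params$nrounds))
      list(nrounds = spec$params$nrounds) else list()
    model_spec(fam, params = params, early_stopping = spec$early_stopping,
               horizon_days = spec$horizon_days, seed = spec$seed + i)
  })
  if (spec$family == "blend_avg") {
    bases <- lapply(base_specs, fit_model, train = train, target = target)
    return(list(bases = bases, meta = NULL))
  }
  set.seed(spec$seed)
  n <- nrow(train)
  hold <- sample.int(n, max(2, floor(0.25 * n)))
  core <- setdiff(seq_len(n), hold)
  if (length(core) < 2) { core <- seq_len(n); hold <- seq_len(n) }
  bases_core <- lapply(base_specs, fit_model,
                       train = train[core, , drop = FALSE], target = target)
  z <- vapply(bases_core, function(m)
    predict(m, train[hold, , drop = FALSE]), numeric(length(hold)))
  z <- matrix(z, ncol = length(bases_core))
  yh <- train[[target]][hold]
  meta <- if (spec$family == "blend_glrm") {
    lam <- 1e-3
    zc <- cbind(1, z)
    beta <- solve(crossprod(zc) + diag(lam * c(0, rep(1, ncol(z)))),
                  crossprod(zc, yh))
    list(kind = "ridge", beta = drop(beta))
  } else {
    set.seed(spec$seed)
    rng <- range(yh); if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
    fit <- nnet::nnet(z, (yh - rng[1]) / diff(rng), size = 16, linout = TRUE,
                      maxit = 500, decay = 1e-4, trace = FALSE)
    list(kind = "nnet", fit = fit, rng = rng)
  }
  # refit bases on the full table for prediction time
  bases <- lapply(base_specs, fit_model, train = train, target = target)
  list(bases = bases, meta = meta)
}

#' Predict with a fitted zoo model
#'
#' Predictions are in days and clipped to `[0, horizon_days]` (default 7:
#' the study predicts discharges within a week). The AVG blender returns
#' exactly the arithmetic mean of its base models' predictions.
#'
#' @param object An `icuflow_model`.
#' @param newdata Feature table with the training schema.
#' @param ... Unused.
#' @return Numeric vector of predicted remaining days.
#' @export
predict.icuflow_model <- function(object, newdata, ...) {
  if (nrow(newdata) == 0) return(numeric(0))
  missing_cols <- setdiff(object$features, names(newdata))
  if (length(missing_cols) > 0)
    stop("schema mismatch: missing feature(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  horizon <- object$spec$horizon_days
  raw <- switch(object$family,
    decision_tree = unname(stats::predict(object$fit, newdata = newdata)),
    gbm_extreme = ,
    gbm_greedy = ,
    gbm_light = {
      x <- feature_matrix(newdata, object$features, object$target)
      stats::predict(object$fit, xgboost::xgb.DMatrix(x))
    },
    sgd_linear = {
      x <- feature_matrix(newdata, object$features, object$target)
      xs <- sweep(sweep(x, 2, object$fit$mu), 2, object$fit$sd, "/")
      drop(xs %*% object$fit$w) + object$fit$b
    },
    blend_avg = {
      preds <- vapply(object$fit$bases, function(m) predict(m, newdata),
                      numeric(nrow(newdata)))
      rowMeans(matrix(preds, ncol = length(object$fit$bases)))
    },
    blend_glrm = ,
    blend_enet = {
      z <- vapply(object$fit$bases, function(m) predict(m, newdata),
                  numeric(nrow(newdata)))
      z <- matrix(z, ncol = length(object$fit$bases))
      meta <- object$fit$meta
      if (meta$kind == "ridge") drop(cbind(1, z) %*% meta$beta)
      else drop(stats::predict(meta$fit, z)) * diff(meta$rng) + meta$rng[1]
    })
  pmin(pmax(as.numeric(raw), 0), horizon)
}

#' Evaluate predictions: residual mean and accuracy
#'
#' The residual mean (RM) is the root-mean-square of the prediction
#' errors; accuracy is the fraction of predictions within
#' `tolerance_days` of the truth (default 1 day — a declared convention,
#' since accuracy for a regressor needs a band).
#'
#' @param predictions,truth Equal-length numeric vectors.
#' @param tolerance_days Absolute-error tolerance defining a "correct"
#'   prediction.
#' @return List with `accuracy`, `residual_mean` and `n`.
#' @export
evaluate_predictions <- function(predictions, truth, tolerance_days = 1) {
  if (length(predictions) != length(truth))
    stop("length mismatch: ", length(predictions), " predictions vs ",
         length(truth), " truths", call. = FALSE)
  if (length(predictions) == 0) stop("empty input", call. = FALSE)
  err <- predictions - truth
  list(accuracy = mean(abs(err) <= tolerance_days),
       residual_mean = sqrt(mean(err^2)),
       n = length(predictions))
}

#' Exhaustive grid search over hyperparameters
#'
#' Fits every combination in the grid on the training table and returns
#' the specification minimizing the validation residual mean. Ties are
#' broken by fewer estimators, then shallower depth, then grid order.
#'
#' @param family Model family (see [model_spec()]).
#' @param grid Named list of hyperparameter value vectors (non-empty).
#' @param train,validation Feature tables.
#' @param target Target column name.
#' @param ... Passed to [model_spec()].
#' @return List with `spec` (winning [model_spec()]), `results` (one row
#'   per combination with its validation residual mean) and `model` (the
#'   winning fitted model).
#' @export
grid_search <- function(family, grid, train, validation,
                        target = "target_days", ...) {
  if (length(grid) == 0 || any(lengths(grid) == 0))
    stop("empty grid", call. = FALSE)
  combos <- expand.grid(grid, stringsAsFactors = FALSE)
  res <- combos
  res$residual_mean <- NA_real_
  fits <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    spec <- model_spec(family, params = as.list(combos[i, , drop = FALSE]),
                       ...)
    fits[[i]] <- fit_model(spec, train, target = target)
    ev <- evaluate_predictions(predict(fits[[i]], validation),
                               validation[[target]])
    res$residual_mean[i] <- ev$residual_mean
  }
  n_est <- if ("nrounds" %in% names(combos)) combos$nrounds else rep(0, nrow(combos))
  depth <- if ("max_depth" %in% names(combos)) combos$max_depth
    else if ("maxdepth" %in% names(combos)) combos$maxdepth
    else rep(0, nrow(combos))
  best <- order(res$residual_mean, n_est, depth)[1]
  list(spec = model_spec(family, params = as.list(combos[best, , drop = FALSE]),
                         ...),
       results = res, model = fits[[best]])
}

#' @export
print.icuflow_model <- function(x, ...) {
  cat("<icuflow_model>", x$family, "on", length(x$features), "features\n")
  invisible(x)
}
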