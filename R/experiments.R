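#' Partition configuration for an experiment
#'
#' The study's partition rows (e.g. validation 18%, cross-validation 36%,
#' holdout 72%) sum past 100%, so they cannot be disjoint splits of one
#' dataset; they are three separate evaluation protocols over the same
#' data: a random validation split, k-fold cross-validation restricted to
#' a random subset, and a holdout evaluation whose training pool is the
#' stated percentage of rows.
#'
#' @param validation_pct,cross_validation_pct,holdout_pct Percentages in
#'   (0, 100]; `holdout_pct` must be < 100 so a test set remains.
#' @param n_folds Folds for the cross-validation protocol (>= 2).
#' @param seed Integer seed making the partitions reproducible.
#' @return A `partition_config`.
#' @export
partition_config <- function(validation_pct, cross_validation_pct,
                             holdout_pct, n_folds = 5L, seed = 1L) {
  for (p in c(validation_pct, cross_validation_pct, holdout_pct))
    if (p <= 0 || p > 100) stop("percentages must lie in (0, 100]",
                                call. = FALSE)
  if (n_folds < 2) stop("n_folds must be >= 2", call. = FALSE)
  structure(list(validation_pct = validation_pct,
                 cross_validation_pct = cross_validation_pct,
                 holdout_pct = holdout_pct, n_folds = as.integer(n_folds),
                 seed = as.integer(seed)),
            class = "partition_config")
}

#' The four partition configurations of the study's experiments
#'
#' @param seed Base seed; each experiment derives its own.
#' @return Named list of four [partition_config()]s.
#' @export
default_experiment_configs <- function(seed = 1L) {
  specs <- list(exp1 = c(18, 36, 72), exp2 = c(18, 36, 80),
                exp3 = c(18, 46, 72), exp4 = c(25, 36, 72))
  out <- lapply(seq_along(specs), function(i)
    partition_config(specs[[i]][1], specs[[i]][2], specs[[i]][3],
                     seed = derive_seed(seed, i)))
  names(out) <- names(specs)
  out
}

#' Build the three evaluation partitions
#'
#' Slice sizes are the largest-remainder rounding of pct x n. The three
#' protocols are drawn independently (same data, different row subsets),
#' deterministically given the config seed.
#'
#' @param table Feature table.
#' @param config A [partition_config()].
#' @return List with `validation` (`train`/`test` row indices), `cv`
#'   (`subset` indices and a `folds` list partitioning the subset) and
#'   `holdout` (`train`/`test`).
#' @export
make_partitions <- function(table, config) {
  stopifnot(inherits(config, "partition_config"))
  n <- nrow(table)
  n_val <- lr_count(config$validation_pct / 100, n)
  n_cv <- lr_count(config$cross_validation_pct / 100, n)
  n_hold <- lr_count(config$holdout_pct / 100, n)
  if (n_val == 0 || n_val == n || n_cv < config$n_folds ||
      n_hold == 0 || n_hold == n)
    stop("infeasible partition percentages for a table of ", n, " rows",
         call. = FALSE)
  set.seed(config$seed)
  val_idx <- sort(sample.int(n, n_val))
  cv_idx <- sort(sample.int(n, n_cv))
  fold_of <- sample(rep_len(seq_len(config$n_folds), n_cv))
  folds <- lapply(seq_len(config$n_folds), function(f) cv_idx[fold_of == f])
  hold_train <- sort(sample.int(n, n_hold))
  list(
    validation = list(train = setdiff(seq_len(n), val_idx), test = val_idx),
    cv = list(subset = cv_idx, folds = folds),
    holdout = list(train = hold_train,
                   test = setdiff(seq_len(n), hold_train))
  )
}

eval_protocols <- function(spec, table, parts, target, tolerance_days) {
  fit_eval <- function(train_idx, test_idx) {
    m <- fit_model(spec, table[train_idx, , drop = FALSE], target = target)
    evaluate_predictions(predict(m, table[test_idx, , drop = FALSE]),
                         table[[target]][test_idx], tolerance_days)
  }
  t0 <- proc.time()[["elapsed"]]
  ev_val <- fit_eval(parts$validation$train, parts$validation$test)
  cv_rms <- vapply(seq_along(parts$cv$folds), function(f) {
    test_idx <- parts$cv$folds[[f]]
    train_idx <- setdiff(parts$cv$subset, test_idx)
    fit_eval(train_idx, test_idx)$residual_mean
  }, 0)
  ev_hold <- fit_eval(parts$holdout$train, parts$holdout$test)
  wall_ms <- (proc.time()[["elapsed"]] - t0) * 1000
  data.frame(
    accuracy = ev_hold$accuracy,
    accuracy_validation = ev_val$accuracy,
    rm_validation = ev_val$residual_mean,
    rm_cv = mean(cv_rms),
    rm_holdout = ev_hold$residual_mean,
    wall_time_ms = wall_ms
  )
}

#' Run the partition experiments over a model zoo
#'
#' For every (experiment config, model) pair, trains and evaluates the
#' model under the three protocols and reports the residual mean per
#' slice, the accuracy (headline column: holdout protocol; validation
#' accuracy is also reported), and an informational wall time. The report
#' is deterministic given the data, zoo and config seeds (timings aside).
#'
#' @param features Encoded, fully observed feature table.
#' @param zoo Named list of [model_spec()]s.
#' @param configs Named list of [partition_config()]s (default: the four
#'   study configurations).
#' @param target Target column name.
#' @param tolerance_days Accuracy tolerance in days.
#' @return Data frame with one row per (experiment, model), of class
#'   `experiment_report`.
#' @export
run_experiments <- function(features, zoo,
                            configs = default_experiment_configs(),
                            target = "target_days", tolerance_days = 1) {
  stopifnot(length(zoo) > 0, length(configs) > 0)
  if (is.null(names(zoo))) names(zoo) <- vapply(zoo, `[[`, "", "family")
  rows <- list()
  for (ei in seq_along(configs)) {
    parts <- make_partitions(features, configs[[ei]])
    for (mi in seq_along(zoo)) {
      ev <- eval_protocols(zoo[[mi]], features, parts, target, tolerance_days)
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(experiment = names(configs)[ei], model = names(zoo)[mi],
                   validation_pct = configs[[ei]]$validation_pct,
                   cross_validation_pct = configs[[ei]]$cross_validation_pct,
                   holdout_pct = configs[[ei]]$holdout_pct),
        ev)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("experiment_report", class(out))
  out
}

#' Render an experiment report as a markdown table
#'
#' @param report An `experiment_report` from [run_experiments()].
#' @return Character vector of markdown lines, invisibly printed.
#' @export
report_markdown <- function(report) {
  hdr <- c("| Experiment | Model | Accuracy | RM validation | RM CV | RM holdout |",
           "|---|---|---|---|---|---|")
  body <- sprintf("| %s (%g/%g/%g) | %s | %.3f | %.5f | %.5f | %.5f |",
                  report$experiment, report$validation_pct,
                  report$cross_validation_pct, report$holdout_pct,
                  report$model, report$accuracy, report$rm_validation,
                  report$rm_cv, report$rm_holdout)
  c(hdr, body)
}
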