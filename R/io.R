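# column-name mapping between internal tables and the MIMIC-style CSVs
BUNDLE_SCHEMA <- list(
  patients = c(subject_id = "SUBJECT_ID", sex = "GENDER", age = "AGE",
               dead_flag = "EXPIRE_FLAG"),
  admissions = c(subject_id = "SUBJECT_ID", hadm_id = "HADM_ID",
                 admission_type = "ADMISSION_TYPE", admit_time = "ADMITTIME",
                 discharge_time = "DISCHTIME", diagnosis = "DIAGNOSIS",
                 admission_location = "ADMISSION_LOCATION",
                 discharge_location = "DISCHARGE_LOCATION",
                 hospital_expire_flag = "HOSPITAL_EXPIRE_FLAG"),
  icustays = c(hadm_id = "HADM_ID", icustay_id = "ICUSTAY_ID",
               in_time = "INTIME", out_time = "OUTTIME", los = "LOS",
               ward_id = "WARD_ID",
               sched_ward_transfer_hour = "SCHED_WARD_TRANSFER_HOUR"),
  prescriptions = c(hadm_id = "HADM_ID", drug = "DRUG",
                    drug_class = "DRUG_CLASS", start_date = "STARTDATE",
                    end_date = "ENDDATE", prod_strength = "PROD_STRENGTH",
                    frequency = "FREQUENCY"),
  chartevents = c(icustay_id = "ICUSTAY_ID", item = "ITEM",
                  time = "CHARTTIME", value = "VALUE",
                  missing_flag = "MISSING_FLAG", true_value = "TRUE_VALUE")
)
BUNDLE_FILES <- c(patients = "PATIENTS.csv", admissions = "ADMISSIONS.csv",
                  icustays = "ICUSTAYS.csv", prescriptions = "PRESCRIPTIONS.csv",
                  chartevents = "CHARTEVENTS.csv")
TIME_COLS <- c("admit_time", "discharge_time", "in_time", "out_time",
               "start_date", "end_date", "time")

#' Write an EHR bundle to CSV files with MIMIC-style column names
#'
#' One UTF-8 CSV per table (PATIENTS, ADMISSIONS, ICUSTAYS, PRESCRIPTIONS,
#' CHARTEVENTS), with upper-case MIMIC column names and ISO-8601
#' timestamps.
#'
#' @param bundle An `ehr_bundle`.
#' @param dir Output directory (created if absent).
#' @return The directory path, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "ehr_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (tb in names(BUNDLE_FILES)) {
    df <- bundle[[tb]]
    for (col in intersect(TIME_COLS, names(df)))
      df[[col]] <- format(df[[col]], "%Y-%m-%dT%H:%M:%S", tz = "UTC")
    if ("dead_flag" %in% names(df)) df$dead_flag <- as.integer(df$dead_flag)
    if ("missing_flag" %in% names(df))
      df$missing_flag <- as.integer(df$missing_flag)
    map <- BUNDLE_SCHEMA[[tb]]
    keep <- intersect(names(map), names(df))
    df <- df[, keep, drop = FALSE]
    names(df) <- unname(map[keep])
    utils::write.csv(df, file.path(dir, BUNDLE_FILES[[tb]]),
                     row.names = FALSE, fileEncoding = "UTF-8")
  }
  invisible(dir)
}

#' Read an EHR bundle written by [write_bundle()]
#'
#' @param dir Directory holding the five CSVs.
#' @return An `ehr_bundle`.
#' @export
read_bundle <- function(dir) {
  out <- list()
  for (tb in names(BUNDLE_FILES)) {
    path <- file.path(dir, BUNDLE_FILES[[tb]])
    if (!file.exists(path)) stop("missing table file: ", path, call. = FALSE)
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
    map <- BUNDLE_SCHEMA[[tb]]
    inv <- stats::setNames(names(map), unname(map))
    names(df) <- ifelse(names(df) %in% names(inv), inv[names(df)], names(df))
    for (col in intersect(TIME_COLS, names(df)))
      df[[col]] <- as.POSIXct(df[[col]], format = "%Y-%m-%dT%H:%M:%S",
                              tz = "UTC")
    if ("dead_flag" %in% names(df)) df$dead_flag <- df$dead_flag == 1
    if ("missing_flag" %in% names(df)) df$missing_flag <- df$missing_flag == 1
    out[[tb]] <- df
  }
  structure(out, class = "ehr_bundle")
}

#' Default model zoo (all eight families)
#'
#' @param seed Base seed (each model derives its own).
#' @param nrounds Boosting rounds cap for the gradient-boosted families
#'   (the printed setting is 2000; smaller caps are useful for quick
#'   runs — early stopping picks the checkpoint either way).
#' @return Named list of [model_spec()]s.
#' @export
default_zoo <- function(seed = 1L, nrounds = 2000) {
  gbm <- function(f, i) model_spec(f, params = list(nrounds = nrounds),
                                   seed = derive_seed(seed, i))
  list(
    sgd_linear = model_spec("sgd_linear", seed = derive_seed(seed, 1)),
    decision_tree = model_spec("decision_tree", seed = derive_seed(seed, 2)),
    gbm_extreme = gbm("gbm_extreme", 3),
    gbm_greedy = gbm("gbm_greedy", 4),
    gbm_light = gbm("gbm_light", 5),
    blend_glrm = model_spec("blend_glrm", params = list(nrounds = nrounds),
                            seed = derive_seed(seed, 6)),
    blend_enet = model_spec("blend_enet", params = list(nrounds = nrounds),
                            seed = derive_seed(seed, 7)),
    blend_avg = model_spec("blend_avg", params = list(nrounds = nrounds),
                           seed = derive_seed(seed, 8))
  )
}

#' Poisson arrival schedule for the flow model
#'
#' @param rates Data frame with columns `pathology`, `route` and `rate`
#'   (mean arrivals per inspection epoch).
#' @param horizon Number of epochs.
#' @param seed Integer seed.
#' @return List of per-epoch arrival data frames for [run_flow()].
#' @export
make_arrival_schedule <- function(rates, horizon, seed = 1L) {
  set.seed(seed)
  lapply(seq_len(horizon), function(t)
    data.frame(pathology = rates$pathology, route = rates$route,
               n = stats::rpois(nrow(rates), rates$rate)))
}

#' Default pipeline configuration
#'
#' One block per stage; every stochastic stage derives its seed from the
#' root seed. The flow block describes three wards (one per diagnosis
#' group) with bed counts proportional to the diagnosis mix and arrival
#' rates split across the three admission routes.
#'
#' @param seed Root integer seed.
#' @return Nested list, YAML-serializable via [write_pipeline_config()].
#' @export
default_pipeline_config <- function(seed = 20120101L) {
  list(
    seed = as.integer(seed),
    cohort = list(use_default = TRUE),
    flow = list(beds = c(12L, 8L, 4L), inspections_per_day = 3L,
                horizon = 120L, mean_icu_los_days = 2.2,
                arrival_rates = list(
                  list(pathology = 1L, route = "EMERGENCY", rate = 0.7),
                  list(pathology = 2L, route = "EMERGENCY", rate = 0.35),
                  list(pathology = 3L, route = "ELECTIVE", rate = 0.1))),
    preprocessing = list(impute = "tree", nibp_missing_rate = 0.3,
                         backfill_offset = 0),
    zoo = list(nrounds = 300L,
               models = c("sgd_linear", "decision_tree", "gbm_light",
                          "blend_avg")),
    experiments = list(tolerance_days = 1,
                       configs = list(exp1 = c(18, 36, 72),
                                      exp2 = c(18, 36, 80),
                                      exp3 = c(18, 46, 72),
                                      exp4 = c(25, 36, 72)))
  )
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @param config Configuration list.
#' @return The configuration list (read) or `path` invisibly (write).
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (block in c("seed", "cohort", "flow", "preprocessing", "zoo",
                  "experiments"))
    if (is.null(cfg[[block]]))
      stop("pipeline config is missing the '", block, "' block", call. = FALSE)
  cfg
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Run the full pipeline: generate, validate, simulate, preprocess,
#' train, report
#'
#' Executes the stages end to end, writing every artifact under
#' `out_dir` along with `manifest.json` recording stage outputs, derived
#' seeds and file hashes. Data artifacts are hash-identical across reruns
#' with the same config and seed.
#'
#' @param config Pipeline configuration list (see
#'   [default_pipeline_config()]) or a YAML path.
#' @param out_dir Output directory.
#' @param seed Root seed (overrides the config's).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config = default_pipeline_config(), out_dir,
                         seed = config$seed) {
  if (is.character(config)) config <- read_pipeline_config(config)
  for (block in c("cohort", "flow", "preprocessing", "zoo", "experiments"))
    if (is.null(config[[block]]))
      stop("pipeline config is missing the '", block, "' block", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage_files <- list()

  ## 1. generate
  ccfg <- if (isTRUE(config$cohort$use_default)) default_config()
          else do.call(cohort_config, config$cohort)
  bundle <- generate_cohort(ccfg, seed = derive_seed(seed, 1))
  bdir <- file.path(out_dir, "bundle")
  write_bundle(bundle, bdir)
  stage_files$generate <- file.path("bundle", BUNDLE_FILES)

  ## 2. validate
  viol <- validate_bundle(bundle)
  if (nrow(viol) > 0) {
    utils::write.csv(viol, file.path(out_dir, "violations.csv"),
                     row.names = FALSE)
    stop("bundle failed validation at stage 'validate': ", nrow(viol),
         " violation(s); see violations.csv", call. = FALSE)
  }
  stage_files$validate <- character(0)

  ## 3. simulate patient flow
  fl <- config$flow
  rates <- do.call(rbind, lapply(fl$arrival_rates, as.data.frame))
  sys <- ward_system(beds = fl$beds,
                     inspections_per_day = fl$inspections_per_day)
  sched <- make_arrival_schedule(rates, fl$horizon,
                                 seed = derive_seed(seed, 3))
  p_dis <- discharge_prob_from_los(fl$mean_icu_los_days,
                                   fl$inspections_per_day)
  traj <- run_flow(sys, sched, p_dis, fl$horizon,
                   seed = derive_seed(seed, 3))
  utils::write.csv(traj$epochs, file.path(out_dir, "flow_epochs.csv"),
                   row.names = FALSE)
  utils::write.csv(traj$wards, file.path(out_dir, "flow_wards.csv"),
                   row.names = FALSE)
  stage_files$simulate <- c("flow_epochs.csv", "flow_wards.csv")

  ## 4. preprocess
  pp <- config$preprocessing
  bundle <- inject_missingness(bundle, pp$nibp_missing_rate,
                               seed = derive_seed(seed, 4))
  feats <- build_features(bundle, impute = pp$impute, encode = TRUE,
                          seed = derive_seed(seed, 4))
  utils::write.csv(feats, file.path(out_dir, "features.csv"),
                   row.names = FALSE)
  jsonlite::write_json(attr(feats, "codebook"),
                       file.path(out_dir, "codebook.json"),
                       auto_unbox = FALSE, pretty = TRUE)
  stage_files$preprocess <- c("features.csv", "codebook.json")

  ## 5. train + 6. experiments
  zoo <- default_zoo(seed = derive_seed(seed, 5),
                     nrounds = config$zoo$nrounds)[config$zoo$models]
  econf <- lapply(seq_along(config$experiments$configs), function(i) {
    v <- config$experiments$configs[[i]]
    partition_config(v[1], v[2], v[3], seed = derive_seed(seed, 10 + i))
  })
  names(econf) <- names(config$experiments$configs)
  report <- run_experiments(feats, zoo, econf,
                            tolerance_days = config$experiments$tolerance_days)
  utils::write.csv(report, file.path(out_dir, "experiment_report.csv"),
                   row.names = FALSE)
  writeLines(report_markdown(report), file.path(out_dir,
                                                "experiment_report.md"))
  stage_files$train <- "experiment_report.csv"
  stage_files$report <- "experiment_report.md"

  data_files <- setdiff(unlist(stage_files), "experiment_report.csv")
  manifest <- list(
    seed = seed,
    stage_seeds = list(generate = derive_seed(seed, 1),
                       simulate = derive_seed(seed, 3),
                       preprocess = derive_seed(seed, 4),
                       train = derive_seed(seed, 5)),
    stages = stage_files,
    hashes = as.list(tools::md5sum(file.path(out_dir,
                                             sort(unlist(stage_files)))))
  )
  names(manifest$hashes) <- sort(unlist(stage_files))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
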