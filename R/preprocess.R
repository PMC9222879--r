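#' Backfill missing non-invasive blood pressure from the invasive channel
#'
#' Non-invasive blood pressure is recorded at a lower frequency; where a
#' reading is flagged missing, the paired invasive reading at the same
#' stay and timestamp (continuously monitored) is substituted, plus a
#' configurable calibration offset. Observed values are never touched.
#' Rows with both channels missing are left `NA` and fall through to
#' median imputation downstream.
#'
#' @param bundle An `ehr_bundle`.
#' @param offset Calibration offset (mmHg) added to the invasive reading.
#' @return The bundle with nibp values backfilled in `chartevents`.
#' @export
backfill_nibp <- function(bundle, offset = 0) {
  stopifnot(inherits(bundle, "ehr_bundle"))
  ce <- bundle$chartevents
  miss <- which(ce$item == "nibp" & is.na(ce$value))
  if (length(miss) == 0) return(bundle)
  ibp <- ce[ce$item == "ibp" & !is.na(ce$value), c("icustay_id", "time", "value")]
  key <- function(id, tm) paste(id, as.numeric(tm))
  ibp_val <- stats::setNames(ibp$value, key(ibp$icustay_id, ibp$time))
  fill <- ibp_val[key(ce$icustay_id[miss], ce$time[miss])]
  ok <- !is.na(fill)
  ce$value[miss[ok]] <- unname(fill[ok]) + offset
  ce$missing_flag[miss[ok]] <- FALSE
  bundle$chartevents <- ce
  bundle
}

#' Median imputation of a numeric column
#'
#' Missing entries are replaced by the median of the observed entries;
#' observed entries are untouched.
#'
#' @param table A data frame.
#' @param column Column name (must be numeric).
#' @return The data frame with the column imputed.
#' @export
impute_median <- function(table, column) {
  x <- table[[column]]
  if (!is.numeric(x)) stop("column '", column, "' is not numeric", call. = FALSE)
  if (all(is.na(x))) stop("cannot impute '", column, "': all values missing",
                          call. = FALSE)
  x[is.na(x)] <- stats::median(x, na.rm = TRUE)
  table[[column]] <- x
  table
}

#' Decision-tree imputation of numeric columns
#'
#' Each numeric column with missing entries is filled by a depth-limited
#' regression tree trained on the rows where it is observed, using the
#' other listed columns as predictors (tree settings: max depth 10,
#' min leaf 4, matching the baseline tree of the model zoo). Columns are
#' processed in ascending order of missingness, one pass, so
#' better-observed columns help the sparser ones. If a column has no
#' complete training rows the median is used instead, with a warning.
#'
#' @param table A data frame.
#' @param columns Numeric columns to impute (default: all numeric columns
#'   containing missing values).
#' @param seed Integer seed (tree fitting is deterministic; the seed fixes
#'   surrogate tie-breaks).
#' @return The data frame with the listed columns fully observed.
#' @export
impute_tree <- function(table, columns = NULL, seed = 1L) {
  num_cols <- names(table)[vapply(table, is.numeric, TRUE)]
  if (is.null(columns))
    columns <- num_cols[vapply(num_cols, function(c) anyNA(table[[c]]), TRUE)]
  if (length(columns) == 0) return(table)
  stopifnot(all(columns %in% num_cols))
  set.seed(seed)
  columns <- columns[order(vapply(columns, function(c) mean(is.na(table[[c]])),
                                  0))]
  for (col in columns) {
    miss <- is.na(table[[col]])
    if (!any(miss)) next
    preds <- setdiff(num_cols, col)
    train <- table[!miss, c(col, preds), drop = FALSE]
    if (nrow(train) == 0 || length(preds) == 0) {
      warning("no complete rows to train tree for '", col,
              "'; falling back to median")
      table <- impute_median(table, col)
      next
    }
    fit <- rpart::rpart(
      stats::reformulate(preds, response = col), data = train,
      method = "anova",
      control = rpart::rpart.control(maxdepth = 10, minbucket = 4,
                                     minsplit = 10, cp = 1e-6, xval = 0))
    table[[col]][miss] <- unname(stats::predict(
      fit, newdata = table[miss, preds, drop = FALSE]))
  }
  table
}

#' Ordinal encoding of categorical columns
#'
#' Each categorical (character or factor) column is mapped to integer
#' codes in first-appearance order, starting at 0. The level-to-code
#' mapping is returned as a codebook so the encoding is invertible;
#' levels unseen at transform time get the reserved code -1 with a
#' warning.
#'
#' @param table A data frame.
#' @param columns Columns to encode (default: all character/factor).
#' @param codebook Optional existing codebook to apply (transform mode).
#' @return List with `table` (encoded) and `codebook` (named list of
#'   character level vectors; code = position - 1).
#' @seealso [decode_categoricals()]
#' @export
encode_categoricals <- function(table, columns = NULL, codebook = NULL) {
  if (is.null(columns))
    columns <- names(table)[vapply(table, function(x)
      is.character(x) || is.factor(x), TRUE)]
  if (is.null(codebook)) {
    codebook <- lapply(stats::setNames(columns, columns), function(col) {
      x <- as.character(table[[col]])
      unique(x[!is.na(x)])
    })
  }
  for (col in columns) {
    x <- as.character(table[[col]])
    code <- match(x, codebook[[col]]) - 1L
    unseen <- !is.na(x) & is.na(code)
    if (any(unseen)) {
      warning("unseen level(s) in '", col, "': ",
              paste(unique(x[unseen]), collapse = ", "),
              "; assigned reserved code -1")
      code[unseen] <- -1L
    }
    table[[col]] <- code
  }
  list(table = table, codebook = codebook)
}

#' Invert an ordinal encoding
#'
#' @param table An encoded data frame.
#' @param codebook Codebook from [encode_categoricals()].
#' @return The data frame with coded columns restored to characters
#'   (reserved code -1 becomes `NA`).
#' @export
decode_categoricals <- function(table, codebook) {
  for (col in names(codebook)) {
    code <- table[[col]]
    x <- rep(NA_character_, length(code))
    valid <- !is.na(code) & code >= 0
    x[valid] <- codebook[[col]][code[valid] + 1L]
    table[[col]] <- x
  }
  table
}

#' Build the flat per-stay feature table
#'
#' Joins the five relational tables into one row per ICU stay with the
#' features the study found informative: discharge location, diagnosis,
#' admission location, primary drug class (first exposed class),
#' prescription strength, drug start/end day-of-month, hospital length of
#' stay, admission and ICU in-hour, out-time day-of-month, the scheduled
#' ward-transfer hour, first-admission flag, and per-stay vitals means.
#' The target `target_days` is the remaining time (days) from ICU
#' admission to ICU out-time — the stay in the one ward, any transfer
#' counting as a discharge.
#'
#' Imputation is applied in the documented order: invasive-BP backfill
#' before aggregation (via [backfill_nibp()], done here when missingness
#' is present), then tree imputation of numeric features, then median for
#' anything the trees could not fill. The returned table carries no
#' missing cells.
#'
#' @param bundle An `ehr_bundle`.
#' @param impute One of "tree" (default), "median" or "none".
#' @param encode Logical; ordinal-encode the categorical columns (default
#'   `FALSE` — encoding is usually deferred to model fitting so the
#'   codebook can be stored alongside the model).
#' @param seed Integer seed passed to [impute_tree()].
#' @return A data frame (one row per `icustay_id`), with attribute
#'   `codebook` when `encode = TRUE`.
#' @export
build_features <- function(bundle, impute = c("tree", "median", "none"),
                           encode = FALSE, seed = 1L) {
  stopifnot(inherits(bundle, "ehr_bundle"))
  impute <- match.arg(impute)
  bundle <- backfill_nibp(bundle)
  adm <- bundle$admissions
  icu <- bundle$icustays
  if (nrow(icu) == 0) return(data.frame())

  i <- match(icu$hadm_id, adm$hadm_id)
  # first admission per subject, by admit time
  ord <- order(adm$subject_id, adm$admit_time)
  first_hadm <- adm$hadm_id[ord][!duplicated(adm$subject_id[ord])]

  pres <- bundle$prescriptions
  cls_order <- unique(pres$drug_class)
  first_rx_idx <- rep(NA_integer_, nrow(icu))
  if (nrow(pres) > 0) {
    pres$.cls_rank <- match(pres$drug_class, cls_order)
    po <- order(pres$hadm_id, pres$.cls_rank)
    pres_first <- pres[po, ][!duplicated(pres$hadm_id[po]), ]
    first_rx_idx <- match(icu$hadm_id, pres_first$hadm_id)
  }
  rx_col <- function(col, default) {
    out <- rep(default, nrow(icu))
    ok <- !is.na(first_rx_idx)
    if (any(ok)) out[ok] <- pres_first[[col]][first_rx_idx[ok]]
    out
  }

  ce <- bundle$chartevents
  vit <- function(item) {
    sub <- ce[ce$item == item & !is.na(ce$value), ]
    if (nrow(sub) == 0) return(rep(NA_real_, nrow(icu)))
    m <- tapply(sub$value, sub$icustay_id, mean)
    unname(m[as.character(icu$icustay_id)])
  }

  mday <- function(t) as.integer(format(t, "%d"))
  hour <- function(t) as.integer(format(t, "%H"))

  feats <- data.frame(
    icustay_id = icu$icustay_id,
    discharge_location = adm$discharge_location[i],
    diagnosis = adm$diagnosis[i],
    admission_location = adm$admission_location[i],
    drug = rx_col("drug_class", "NONE"),
    out_time_day = mday(icu$out_time),
    prod_strength = rx_col("prod_strength", "NONE"),
    drug_start_day = {x <- rx_col("start_date", NA_real_)
                      ifelse(is.na(x), NA_integer_,
                             mday(as.POSIXct(x, origin = "1970-01-01",
                                             tz = "UTC")))},
    los = as.numeric(difftime(adm$discharge_time[i], adm$admit_time[i],
                              units = "days")),
    drug_end_day = {x <- rx_col("end_date", NA_real_)
                    ifelse(is.na(x), NA_integer_,
                           mday(as.POSIXct(x, origin = "1970-01-01",
                                           tz = "UTC")))},
    admission_hour = hour(adm$admit_time[i]),
    first_admission_flag = as.integer(icu$hadm_id %in% first_hadm),
    icu_in_hour = hour(icu$in_time),
    expected_ward_transfer_hour = icu$sched_ward_transfer_hour,
    heart_rate_mean = vit("heart_rate"),
    resp_rate_mean = vit("resp_rate"),
    nibp_mean = vit("nibp"),
    target_days = icu$los,
    stringsAsFactors = FALSE
  )

  num_feats <- setdiff(names(feats)[vapply(feats, is.numeric, TRUE)],
                       c("icustay_id", "target_days"))
  if (impute != "none") {
    if (impute == "tree") feats <- impute_tree(feats, columns =
      num_feats[vapply(num_feats, function(c) anyNA(feats[[c]]), TRUE)],
      seed = seed)
    for (col in num_feats) if (anyNA(feats[[col]]))
      feats <- impute_median(feats, col)
  }
  if (encode) {
    enc <- encode_categoricals(feats)
    feats <- enc$table
    attr(feats, "codebook") <- enc$codebook
  }
  feats
}

#' Correlation screen over numeric features
#'
#' Optional feature-selection step: scans the pairwise Pearson
#' correlations of the numeric feature columns and drops the later column
#' of any pair whose absolute correlation exceeds the threshold, keeping
#' the target untouched.
#'
#' @param table Feature table.
#' @param threshold Absolute-correlation cutoff (default 0.95).
#' @param target Target column, never dropped.
#' @return The table without the dropped columns; the dropped names are
#'   attached as attribute `dropped`.
#' @export
drop_correlated <- function(table, threshold = 0.95, target = "target_days") {
  num <- setdiff(names(table)[vapply(table, is.numeric, TRUE)],
                 c("icustay_id", target))
  dropped <- character(0)
  if (length(num) >= 2) {
    cm <- abs(stats::cor(table[, num, drop = FALSE],
                         use = "pairwise.complete.obs"))
    for (j in seq_along(num)[-1]) {
      keep <- setdiff(num[seq_len(j - 1)], dropped)
      if (length(keep) && any(cm[keep, num[j]] > threshold, na.rm = TRUE))
        dropped <- c(dropped, num[j])
    }
  }
  out <- table[, setdiff(names(table), dropped), drop = FALSE]
  attr(out, "dropped") <- dropped
  out
}

#' Split-gain feature importance
#'
#' Per-feature mean training-loss reduction over all splits of a fitted
#' tree ensemble, reported two ways: rescaled so the top feature reads
#' 100% (`gain_pct`), and normalized to sum to one (`gain_share`). A
#' model with no splits yields all-zero importances.
#'
#' @param fitted A fitted model from [fit_model()] (tree or gradient
#'   boosted families), an `xgb.Booster`, or an `rpart` fit.
#' @param feature_names Feature names to report (defaults to those stored
#'   with the model); features never used get weight 0.
#' @return Data frame (`feature`, `gain_pct`, `gain_share`) sorted by
#'   decreasing weight.
#' @export
feature_importance <- function(fitted, feature_names = NULL) {
  if (inherits(fitted, "icuflow_model")) {
    if (is.null(feature_names)) feature_names <- fitted$features
    fitted <- fitted$fit
  }
  gains <- NULL
  if (inherits(fitted, "xgb.Booster")) {
    imp <- tryCatch(xgboost::xgb.importance(model = fitted),
                    error = function(e) NULL)
    gains <- if (is.null(imp) || nrow(imp) == 0) numeric(0)
      else stats::setNames(imp$Gain, imp$Feature)
  } else if (inherits(fitted, "rpart")) {
    vi <- fitted$variable.importance
    gains <- if (is.null(vi)) numeric(0) else vi
  } else stop("unsupported model type for feature_importance", call. = FALSE)
  if (is.null(feature_names)) feature_names <- names(gains)
  g <- stats::setNames(rep(0, length(feature_names)), feature_names)
  common <- intersect(names(gains), feature_names)
  g[common] <- gains[common]
  out <- data.frame(feature = names(g), gain_pct = if (max(g) > 0)
    100 * g / max(g) else g, gain_share = if (sum(g) > 0) g / sum(g) else g,
    row.names = NULL)
  out[order(-out$gain_pct), , drop = FALSE]
}
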