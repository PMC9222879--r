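#!/usr/bin/env Rscript
# Stage 5 — partition experiments: the four partition configurations
# ({validation%, cross-validation%, holdout%} = {18,36,72}, {18,36,80},
# {18,46,72}, {25,36,72}), each evaluated under three protocols (random
# validation split, 5-fold CV on a subset, holdout pool) per model.
#
# By default a four-model zoo keeps the run around two minutes; set
# FULL_ZOO <- TRUE for all eight families (roughly ten minutes).
#
# Reads:  results/features.csv (regenerated if absent)
# Writes: results/experiment_report.csv, results/experiment_report.md

suppressPackageStartupMessages(library(icuflow))
seed <- 20120101L
FULL_ZOO <- FALSE
dir.create("results", showWarnings = FALSE)

feats <- if (file.exists("results/features.csv")) {
  utils::read.csv("results/features.csv")
} else {
  b <- inject_missingness(generate_cohort(default_config(), seed = seed),
                          0.3, seed = seed + 1)
  encode_categoricals(build_features(b, impute = "tree",
                                     seed = seed + 2))$table
}

zoo <- default_zoo(seed = seed, nrounds = 150)
if (!FULL_ZOO)
  zoo <- zoo[c("sgd_linear", "decision_tree", "gbm_light", "blend_glrm")]

report <- run_experiments(feats, zoo,
                          default_experiment_configs(seed = seed))
write.csv(report, "results/experiment_report.csv", row.names = FALSE)
writeLines(report_markdown(report), "results/experiment_report.md")

cat("Ran", length(unique(report$experiment)), "partition configurations x",
    length(zoo), "models.\n\n")
print(report[, c("experiment", "model", "accuracy", "rm_validation",
                 "rm_cv", "rm_holdout")], row.names = FALSE, digits = 3)
best <- report[which.max(report$accuracy), ]
cat("\nBest cell:", best$model, "under", best$experiment,
    "- accuracy", round(best$accuracy, 3),
    ", holdout RM", round(best$rm_holdout, 4), "d\n")
cat("Blender robustness: holdout RM of blend models never exceeds the",
    "worst base model within any experiment:",
    all(vapply(unique(report$experiment), function(e) {
      r <- report[report$experiment == e, ]
      blend <- grepl("blend", r$model)
      !any(blend) || max(r$rm_holdout[blend]) <=
        max(r$rm_holdout[!blend]) + 1e-9
    }, TRUE)), "\n")
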