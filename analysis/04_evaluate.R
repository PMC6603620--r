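#!/usr/bin/env Rscript
# Stage 4: fit the four calibration regressors and evaluate them.
#
# MLR, log-transformed MNLR, a 15-hidden-unit identity-activation ELM and a
# 500-tree random forest (mtry = 4) are fitted on the pruned calibration
# features, validated by 10-fold cross-validation (pooled held-out RMSE) and
# tested on the beverage panel: per-beverage aggregated predictions, percent
# errors against the labeled contents, and the +/-0.5 % v/v normative
# tolerance flags. The identity-activation ELM is expected to track MLR's
# predictions almost exactly; the random forest interpolates the calibration
# grid. This stage dominates the runtime (10-fold CV of the forest).

suppressPackageStartupMessages(library(enosebeer))

SEED <- 1L

read_features <- function(path) {
  feats <- utils::read.csv(path, check.names = FALSE)
  meta_cols <- c("label_abv", "sample_id", "measurement_id")
  list(features = feats[, setdiff(names(feats), meta_cols)],
       labels = feats$label_abv, sample_id = feats$sample_id,
       measurement_id = feats$measurement_id)
}
pc <- read_features("results/features_calibration.csv")
pt <- read_features("results/features_test.csv")

model_configs <- default_model_configs(SEED + 3L)
model_configs$RF$seed <- SEED + 4L
report <- build_report(pc, pt, model_configs = model_configs,
                       cv_k = 10, cv_seed = SEED + 2L,
                       alpha = 0.05, tolerance = 0.5)
print(report)
message(sprintf("beverages within +/-0.5 %% v/v of label: %s",
                paste(sprintf("%s %d/7", names(model_configs),
                              vapply(names(model_configs), function(mk)
                                sum(report$per_beverage$within_tolerance[
                                  report$per_beverage$model == mk]),
                                integer(1))),
                      collapse = ", ")))

write_report(report, "results")
message("written: results/rmse_summary.csv, results/percent_error.csv, results/report.json")
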