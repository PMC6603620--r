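#!/usr/bin/env Rscript
# Stage 2: preprocess raw voltages into the per-record feature matrix.
#
# Chain per sensor channel: outlier-gated trailing moving average (window 50,
# 3-sigma gate) on the voltage signal, divider conversion to resistance,
# temperature/humidity compensation with each record's own ambient
# covariates, then min-max normalization. The normalizer is fitted on the
# calibration set only and frozen before it touches the test set.

suppressPackageStartupMessages(library(enosebeer))

reg <- sensor_registry()
cal <- read_dataset("results/data/calibration.csv", reg)
tst <- read_dataset("results/data/test.csv", reg)

pc <- preprocess_pipeline(cal, reg)
pt <- preprocess_pipeline(tst, reg, normalizer = pc$normalizer)
message(sprintf("features: %d calibration rows, %d test rows, %d sensors",
                nrow(pc$features), nrow(pt$features), ncol(pc$features)))
message(sprintf("calibration features span [%.3f, %.3f]; test features span [%.3f, %.3f] (not clipped)",
                min(as.matrix(pc$features)), max(as.matrix(pc$features)),
                min(as.matrix(pt$features)), max(as.matrix(pt$features))))

write_features <- function(p, path) {
  out <- cbind(p$features,
               data.frame(label_abv = p$labels, sample_id = p$sample_id,
                          measurement_id = p$measurement_id,
                          check.names = FALSE))
  utils::write.csv(out, path, row.names = FALSE)
}
write_features(pc, "results/features_calibration.csv")
write_features(pt, "results/features_test.csv")
jsonlite::write_json(list(min = as.list(pc$normalizer$min),
                          max = as.list(pc$normalizer$max)),
                     "results/normalizer.json", auto_unbox = TRUE, digits = NA)
message("written: results/features_*.csv, results/normalizer.json")
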