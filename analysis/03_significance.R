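#!/usr/bin/env Rscript
# Stage 3: per-sensor significance screening on the calibration features.
#
# An OLS fit of the % v/v labels on all 13 sensors supplies each sensor's
# coefficient t-test p-value (the 1-df partial F-test); sensors whose
# p-value exceeds 0.05 do not contribute significantly and are pruned from
# every downstream model. The bundled reference p-values from a prior
# calibration of this array prune MQ-135 and TGS822 at the same rule,
# leaving 11 of the 13 channels.

suppressPackageStartupMessages(library(enosebeer))

feats <- utils::read.csv("results/features_calibration.csv",
                         check.names = FALSE)
meta_cols <- c("label_abv", "sample_id", "measurement_id")
X <- feats[, setdiff(names(feats), meta_cols)]
y <- feats$label_abv

sig <- sensor_significance(X, y, alpha = 0.05)
print(sig)

ref <- reference_sensor_pvalues()
ref_sig <- significance_report(setNames(ref$p_value, ref$name), alpha = 0.05)
message(sprintf("reference pruning: %d retained, removes %s",
                length(ref_sig$retained),
                paste(ref_sig$removed, collapse = " and ")))

tab <- data.frame(sensor = names(sig$p_values),
                  p_value = unname(sig$p_values),
                  retained = names(sig$p_values) %in% sig$retained,
                  reference_p_value = ref$p_value[match(names(sig$p_values),
                                                        ref$name)],
                  row.names = NULL)
utils::write.csv(tab, "results/sensor_significance.csv", row.names = FALSE)
message("written: results/sensor_significance.csv")
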