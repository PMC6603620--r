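#!/usr/bin/env Rscript
# Stage 1: simulate the calibration and beverage-test acquisitions.
#
# The calibration design measures 15 ethanol/water standards (1-8 % v/v)
# in six runs spread over three ambient conditions, 8 min per measurement
# at 1 sample/s; the test stage measures the 7-beer panel twice at
# ~30 C / 41 %RH. Expected arithmetic: 480 records per measurement,
# 2,880 per concentration, 43,200 calibration records, 6,720 test records.

suppressPackageStartupMessages(library(enosebeer))

SEED <- 1L
dir.create("results/data", showWarnings = FALSE, recursive = TRUE)

reg <- sensor_registry()
design <- protocol_design()

cal <- simulate_calibration_dataset(design, simulation_config(seed = SEED), reg)
message(sprintf("calibration: %d records in %d measurements (%d each), %d concentrations",
                nrow(cal), count_measurements(cal),
                nrow(cal) / count_measurements(cal),
                length(unique(cal$label_abv))))

tst <- simulate_test_dataset(beverage_panel(), 2, design,
                             simulation_config(seed = SEED + 1L), reg)
message(sprintf("test: %d records in %d measurements (%d beverages x 2 bottles)",
                nrow(tst), count_measurements(tst),
                length(unique(tst$sample_id))))

write_dataset(cal, "results/data/calibration.csv")
write_dataset(tst, "results/data/test.csv")
message("written: results/data/calibration.csv, results/data/test.csv")
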