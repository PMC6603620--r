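#' Per-beverage parameter-recovery errors
#'
#' Runs the calibration/test protocol end to end for the linear-family models
#' and returns each simulated beverage's aggregated prediction error against
#' its true ethanol content. Used to check that the pipeline recovers the
#' generating concentrations: beverage-level errors should sit within the
#' +/-0.5 % v/v labeling tolerance at the default noise level and collapse
#' to numerical noise when `noise_sd = 0`.
#'
#' @param seed Base seed (calibration simulation: `seed`; test simulation:
#'   `seed + 1`; ELM weights: `seed + 3`).
#' @param noise_sd Per-reading log-scale noise; `NULL` keeps the simulator
#'   default.
#' @param design A [protocol_design()].
#' @param panel Beverage panel; defaults to the bundled panel with all VOC
#'   multipliers neutralised to 1 so that the effective concentration equals
#'   the true content.
#' @param models Character subset of `c("MLR", "MNLR", "ELM", "RF")`.
#' @param alpha Sensor-pruning significance level.
#' @return Data frame with columns `model`, `beverage`, `true_abv`,
#'   `predicted_abv`, `error` (predicted minus true).
#' @export
recovery_errors <- function(seed, noise_sd = NULL,
                            design = protocol_design(),
                            panel = NULL,
                            models = c("MLR", "ELM"),
                            alpha = 0.05) {
  registry <- sensor_registry()
  if (is.null(panel)) {
    panel <- beverage_panel()
    panel$voc_multiplier <- 1
  }
  sim_cal <- simulation_config(seed = seed)
  if (!is.null(noise_sd)) sim_cal$noise_sd <- noise_sd
  sim_test <- sim_cal
  sim_test$seed <- as.integer(seed + 1)

  cal <- simulate_calibration_dataset(design, sim_cal, registry)
  tst <- simulate_test_dataset(panel, 2, design, sim_test, registry)
  pc <- preprocess_pipeline(cal, registry)
  pt <- preprocess_pipeline(tst, registry, normalizer = pc$normalizer)

  sig <- sensor_significance(pc$features, pc$labels, alpha)
  Xc <- pc$features[, sig$retained, drop = FALSE]
  Xt <- pt$features[, sig$retained, drop = FALSE]

  cfgs <- default_model_configs(seed + 3L)[models]
  rows <- lapply(names(cfgs), function(nm) {
    model <- fit_model(cfgs[[nm]], Xc, pc$labels)
    agg <- aggregate_by_sample(predict(model, Xt), pt$sample_id)
    truth <- panel$true_abv[match(names(agg), panel$name)]
    data.frame(model = nm, beverage = names(agg), true_abv = truth,
               predicted_abv = unname(agg), error = unname(agg) - truth,
               row.names = NULL)
  })
  do.call(rbind, rows)
}
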