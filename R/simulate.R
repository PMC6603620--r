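#' Calibration/test experimental design
#'
#' Describes the measurement protocol used to calibrate the array: a set of
#' ethanol/water standard solutions, a set of experimental runs at stated
#' ambient conditions, and the acquisition timing. The defaults reproduce the
#' study protocol: 15 standards between 1 and 8 % v/v, six runs (two per day
#' at 25 C/33 %RH, 25 C/27 %RH and 27 C/31 %RH), 8 minutes per measurement at
#' 1 sample/s, after a ~10 minute sensor preheat whose transient samples are
#' not recorded.
#'
#' @param concentrations Ethanol contents of the standard solutions, % v/v.
#' @param runs Data frame of runs with columns `temperature_c`,
#'   `humidity_pct`, `pressure_hpa`.
#' @param duration_s Recorded seconds per measurement.
#' @param rate_hz Samples per second.
#' @param warmup_s Preheat seconds elapsed before the first recorded sample;
#'   emitted time stamps start at `warmup_s`.
#' @return A `protocol_design` list.
#' @export
protocol_design <- function(concentrations = c(1, 1.5, 2, 2.5, 3, 3.5, 3.7,
                                               3.9, 4.1, 4.3, 4.5, 5, 5.5, 6, 8),
                            runs = data.frame(
                              temperature_c = c(25, 25, 25, 25, 27, 27),
                              humidity_pct  = c(33, 33, 27, 27, 31, 31),
                              pressure_hpa  = 1013
                            ),
                            duration_s = 480,
                            rate_hz = 1,
                            warmup_s = 600) {
  if (length(concentrations) < 1) stop("design needs at least one concentration")
  if (any(concentrations < 0)) stop("concentrations must be non-negative")
  if (!is.data.frame(runs) || nrow(runs) < 1) stop("design needs at least one run")
  stopifnot(all(c("temperature_c", "humidity_pct", "pressure_hpa") %in% names(runs)))
  if (duration_s <= 0 || rate_hz <= 0) stop("duration_s and rate_hz must be positive")
  if (warmup_s < 0) stop("warmup_s must be non-negative")
  structure(list(concentrations = concentrations, runs = runs,
                 duration_s = duration_s, rate_hz = rate_hz,
                 warmup_s = warmup_s),
            class = "protocol_design")
}

#' Simulated beverage test panel
#'
#' The default panel is the seven commercial beers used to test the models,
#' identified by their labeled alcohol content (C4, C4M, C4.5, C4.6, C5,
#' C5.4, C7.9). `true_abv` is the ethanol content the simulator uses;
#' `voc_multiplier >= 1` inflates the effective concentration seen by the
#' sensors, lumping non-ethanol volatiles (the dark Malzbier C4M emits more
#' VOCs than the equally-labeled C4, so its default multiplier exceeds 1).
#'
#' @param path Optional CSV path; defaults to the bundled panel.
#' @return A data frame with columns `name`, `description`, `true_abv`,
#'   `labeled_abv`, `voc_multiplier`.
#' @export
beverage_panel <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "beverage_panel.csv", package = "enosebeer")
  }
  panel <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "true_abv", "labeled_abv", "voc_multiplier") %in% names(panel)))
  if (any(panel$voc_multiplier < 1)) stop("voc_multiplier must be >= 1")
  panel
}

# Per-sensor forward-model defaults: baseline resistance in clean air (ohms)
# and the power-law concentration response R = r0 * (1 + k*c)^(-gamma).
# MQ-3 is the most ethanol-sensitive channel; its defaults put the steady
# divider voltage near 0.8 V at 1 % v/v rising to ~3.1 V at 8 % v/v.
default_sensor_response <- function() {
  data.frame(
    name  = c("MQ-2", "MQ-3", "MQ-4", "MQ-5", "MQ-6", "MQ-7", "MQ-8", "MQ-9",
              "MQ-135", "TGS822", "TGS2600", "TGS2602", "TGS2603"),
    baseline_r0   = c(60000, 240000, 45000, 50000, 48000, 40000, 35000, 30000,
                      55000, 80000, 70000, 65000, 50000),
    sensitivity_k = c(0.9, 2.0, 0.5, 0.6, 0.55, 0.4, 0.35, 0.3,
                      0.7, 1.0, 0.8, 0.75, 0.6),
    gamma         = c(0.80, 1.23, 0.60, 0.65, 0.62, 0.55, 0.50, 0.45,
                      0.70, 0.90, 0.75, 0.72, 0.68),
    stringsAsFactors = FALSE
  )
}

#' Simulator configuration
#'
#' @param seed Integer seed; the same seed, design and config produce a
#'   bit-identical dataset.
#' @param noise_sd Relative (log-scale) noise per reading on the sensor
#'   resistance. The default 0.1 gives record-level prediction scatter of a
#'   few tenths of a percent v/v after filtering, the same order as the
#'   errors of the physical device.
#' @param noise_model `"lognormal"` (multiplicative on resistance, the
#'   default: resistances are positive) or `"additive"` (Gaussian on the
#'   output voltage with sd `noise_sd` volts).
#' @param response Data frame with per-sensor columns `name`, `baseline_r0`
#'   (ohms in clean air), `sensitivity_k` and `gamma` (both `> 0`) of the
#'   power-law concentration response.
#' @param tau_s Warm-up time constant in seconds of the first-order transient
#'   `1 + exp(-t / tau_s)` multiplying the resistance (t measured from
#'   power-on).
#' @param test_temperature_c,test_humidity_pct,test_pressure_hpa Ambient
#'   conditions of the beverage test stage (default ~30 C / 41 %RH).
#' @param v_cc Divider supply voltage in volts.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(seed = 1,
                              noise_sd = 0.1,
                              noise_model = c("lognormal", "additive"),
                              response = default_sensor_response(),
                              tau_s = 120,
                              test_temperature_c = 30,
                              test_humidity_pct = 41,
                              test_pressure_hpa = 1013,
                              v_cc = 5) {
  noise_model <- match.arg(noise_model)
  stopifnot(all(c("name", "baseline_r0", "sensitivity_k", "gamma") %in% names(response)))
  if (any(response$sensitivity_k <= 0) || any(response$gamma <= 0)) {
    stop("sensitivity_k and gamma must be positive for every sensor")
  }
  if (any(response$baseline_r0 <= 0)) stop("baseline_r0 must be positive")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (tau_s <= 0) stop("tau_s must be positive")
  structure(list(seed = as.integer(seed), noise_sd = noise_sd,
                 noise_model = noise_model, response = response,
                 tau_s = tau_s,
                 test_temperature_c = test_temperature_c,
                 test_humidity_pct = test_humidity_pct,
                 test_pressure_hpa = test_pressure_hpa,
                 v_cc = v_cc),
            class = "simulation_config")
}

# Draws one measurement from the current RNG stream. Forward model per sensor:
#   R_true = r0 * (1 + k * conc)^(-gamma)
#   R_obs(t) = R_true * D(T, RH) * (1 + exp(-t/tau)) * noise(t)
# with D the compensation denominator, so dividing an observed resistance by
# D recovers R_true * transient * noise exactly. Voltages via the divider.
simulate_measurement_core <- function(conc, temperature_c, humidity_pct,
                                      pressure_hpa, config, design, registry,
                                      sample_id, measurement_id, label_abv = NA) {
  n <- as.integer(round(design$duration_s * design$rate_hz))
  t <- design$warmup_s + (seq_len(n) - 1) / design$rate_hz
  transient <- 1 + exp(-t / config$tau_s)
  volt <- matrix(NA_real_, n, nrow(registry))
  colnames(volt) <- registry$name
  for (i in seq_len(nrow(registry))) {
    spec <- registry[i, , drop = FALSE]
    resp <- config$response[match(spec$name, config$response$name), ]
    if (is.na(resp$name)) stop("no response parameters for sensor ", spec$name)
    r_true <- resp$baseline_r0 * (1 + resp$sensitivity_k * conc)^(-resp$gamma)
    d <- compensation_denominator(spec, temperature_c, humidity_pct)
    if (d <= 0) stop("ambient conditions outside calibrated envelope for ", spec$name)
    r_obs <- r_true * d * transient
    if (config$noise_model == "lognormal") {
      if (config$noise_sd > 0) {
        r_obs <- r_obs * exp(stats::rnorm(n, 0, config$noise_sd))
      }
      v <- resistance_to_voltage(r_obs, spec, config$v_cc)
    } else {
      v <- resistance_to_voltage(r_obs, spec, config$v_cc)
      if (config$noise_sd > 0) v <- v + stats::rnorm(n, 0, config$noise_sd)
    }
    volt[, i] <- v
  }
  out <- data.frame(time_s = t, check.names = FALSE)
  out <- cbind(out, as.data.frame(volt, check.names = FALSE))
  out$temperature_c <- temperature_c
  out$humidity_pct <- humidity_pct
  out$pressure_hpa <- pressure_hpa
  out$sample_id <- sample_id
  out$measurement_id <- measurement_id
  out$label_abv <- label_abv
  out
}

#' Simulate a single sensor-array measurement
#'
#' @param conc Ethanol concentration of the headspace source, % v/v (`>= 0`).
#' @param condition Length-two numeric `(temperature_c, humidity_pct)`.
#' @param config A [simulation_config()].
#' @param design A [protocol_design()] (supplies timing).
#' @param registry Sensor registry.
#' @param sample_id,measurement_id,label_abv Identifiers attached to each row.
#' @return A data frame of `duration_s * rate_hz` rows in the dataset schema
#'   (see [read_dataset()]).
#' @export
simulate_measurement <- function(conc, condition, config = simulation_config(),
                                 design = protocol_design(),
                                 registry = sensor_registry(),
                                 sample_id = "sample", measurement_id = "m1",
                                 label_abv = NA) {
  if (conc < 0) stop("concentration must be non-negative")
  withr::with_seed(config$seed,
    simulate_measurement_core(conc, condition[1], condition[2],
                              1013, config, design, registry,
                              sample_id, measurement_id, label_abv))
}

#' Simulate the full calibration dataset
#'
#' One measurement per (run x concentration) of the design: with the default
#' protocol, 480 records per measurement, 2,880 per concentration and 43,200
#' in total. Every record carries its % v/v label and the ambient covariates
#' of its run.
#'
#' @param design A [protocol_design()].
#' @param config A [simulation_config()].
#' @param registry Sensor registry.
#' @return A dataset data frame (see [read_dataset()] for the schema).
#' @export
simulate_calibration_dataset <- function(design = protocol_design(),
                                         config = simulation_config(),
                                         registry = sensor_registry()) {
  if (length(design$concentrations) == 0 || nrow(design$runs) == 0) {
    stop("empty design")
  }
  withr::with_seed(config$seed, {
    parts <- vector("list", nrow(design$runs) * length(design$concentrations))
    idx <- 0
    for (r in seq_len(nrow(design$runs))) {
      run <- design$runs[r, ]
      for (conc in design$concentrations) {
        idx <- idx + 1
        parts[[idx]] <- simulate_measurement_core(
          conc, run$temperature_c, run$humidity_pct, run$pressure_hpa,
          config, design, registry,
          sample_id = sprintf("cal_%g", conc),
          measurement_id = sprintf("run%02d_c%g", r, conc),
          label_abv = conc)
      }
    }
    do.call(rbind, parts)
  })
}

#' Simulate the beverage test dataset
#'
#' Measures each beverage `bottles_per_beer` times at the test-stage ambient
#' conditions of `config`. The effective concentration seen by the sensors is
#' `true_abv * voc_multiplier`; the recorded label is `labeled_abv`.
#'
#' @param beers A beverage panel data frame (see [beverage_panel()]).
#' @param bottles_per_beer Measurements per beverage (`>= 1`), default 2.
#' @param design A [protocol_design()] (timing only).
#' @param config A [simulation_config()].
#' @param registry Sensor registry.
#' @return A dataset data frame: `nrow(beers) * bottles_per_beer`
#'   measurements (6,720 records under the defaults).
#' @export
simulate_test_dataset <- function(beers = beverage_panel(),
                                  bottles_per_beer = 2,
                                  design = protocol_design(),
                                  config = simulation_config(),
                                  registry = sensor_registry()) {
  if (!is.data.frame(beers) || nrow(beers) == 0) stop("empty beverage list")
  if (bottles_per_beer < 1) stop("bottles_per_beer must be >= 1")
  withr::with_seed(config$seed, {
    parts <- list()
    idx <- 0
    for (b in seq_len(nrow(beers))) {
      eff <- beers$true_abv[b] * beers$voc_multiplier[b]
      for (bot in seq_len(bottles_per_beer)) {
        idx <- idx + 1
        parts[[idx]] <- simulate_measurement_core(
          eff, config$test_temperature_c, config$test_humidity_pct,
          config$test_pressure_hpa, config, design, registry,
          sample_id = beers$name[b],
          measurement_id = sprintf("%s_bottle%d", beers$name[b], bot),
          label_abv = beers$labeled_abv[b])
      }
    }
    do.call(rbind, parts)
  })
}
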