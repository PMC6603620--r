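#' Load the MOS sensor registry
#'
#' Reads a sensor registry file: one row per metal-oxide gas sensor with its
#' load resistance and the six polynomial constants of the ambient
#' (temperature/humidity) response-compensation model fitted to the
#' manufacturers' characteristic curves. The constants are consumed as given;
#' the `fit_r2` column is informational metadata about that original fit.
#'
#' @param path Path to a registry CSV. Defaults to the registry bundled with
#'   the package (13 sensors: nine Hanwei MQ-series, four Figaro TGS-series,
#'   all read through 10 kOhm load resistors).
#' @return A `sensor_registry` data frame with columns `name`,
#'   `sensitive_gases` (semicolon-separated), `load_resistance_ohm`,
#'   `alpha0`, `alpha1`, `beta0`, `beta1`, `delta`, `xi`, `fit_r2`.
#' @export
load_sensor_registry <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "sensor_registry.csv", package = "enosebeer")
  }
  if (!file.exists(path)) stop("sensor registry file not found: ", path)
  reg <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  required <- c("name", "sensitive_gases", "load_resistance_ohm",
                "alpha0", "alpha1", "beta0", "beta1", "delta", "xi", "fit_r2")
  missing <- setdiff(required, names(reg))
  if (length(missing) > 0) {
    stop("sensor registry is missing columns: ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(reg$name)) stop("sensor registry has duplicated sensor names")
  if (any(reg$load_resistance_ohm <= 0)) stop("load_resistance_ohm must be positive")
  if (any(reg$xi <= 0)) stop("all registry xi constants must be positive")
  class(reg) <- c("sensor_registry", "data.frame")
  reg
}

#' The bundled 13-sensor registry
#'
#' @return The default `sensor_registry` (13 rows). The bundled file is
#'   validated on load: unique names, positive load resistance, positive `xi`.
#' @export
sensor_registry <- function() {
  reg <- load_sensor_registry()
  if (nrow(reg) != 13) stop("bundled sensor registry must contain exactly 13 sensors")
  reg
}

#' Look up one sensor's specification
#'
#' @param registry A `sensor_registry`.
#' @param name Sensor name, e.g. `"MQ-3"`.
#' @return A one-row data frame (the sensor's spec).
#' @export
sensor_spec <- function(registry, name) {
  i <- match(name, registry$name)
  if (is.na(i)) stop("unknown sensor: ", name)
  registry[i, , drop = FALSE]
}

#' Ambient compensation denominator
#'
#' Evaluates the six-term polynomial
#' `alpha0*x0 + alpha1*x0^2 + beta0*x1 + beta1*x1^2 + delta*x0*x1 + xi`
#' in temperature `x0` (degrees C) and relative humidity `x1` (%). This is the
#' denominator of the response-compensation transform: dividing a measured
#' resistance by it removes the sensor's ambient dependence. The full
#' polynomial is always evaluated even where some constants are zero.
#'
#' @param spec A one-row sensor spec (see [sensor_spec()]) or any list with
#'   fields `alpha0`, `alpha1`, `beta0`, `beta1`, `delta`, `xi`.
#' @param x0 Temperature in degrees Celsius (vectorised).
#' @param x1 Relative humidity in percent (vectorised).
#' @return The denominator value(s), dimensionless.
#' @export
compensation_denominator <- function(spec, x0, x1) {
  stopifnot(all(is.finite(x0)), all(is.finite(x1)))
  spec$alpha0 * x0 + spec$alpha1 * x0^2 +
    spec$beta0 * x1 + spec$beta1 * x1^2 +
    spec$delta * x0 * x1 + spec$xi
}

#' Compensate a measured resistance for temperature and humidity
#'
#' Returns `r_s / compensation_denominator(spec, x0, x1)`. The transform is
#' strictly linear (homogeneous of degree one) in `r_s` at fixed ambient
#' conditions.
#'
#' @param spec One-row sensor spec.
#' @param r_s Measured sensor resistance in ohms (vectorised, `>= 0`).
#' @param x0 Temperature in degrees Celsius.
#' @param x1 Relative humidity in percent, in `[0, 100]`.
#' @return Compensated resistance in ohms.
#' @export
compensate <- function(spec, r_s, x0, x1) {
  if (any(r_s < 0)) stop("measured resistance r_s must be non-negative")
  if (any(x1 < 0 | x1 > 100)) stop("relative humidity x1 must lie in [0, 100]")
  d <- compensation_denominator(spec, x0, x1)
  if (any(d <= 0)) {
    stop("compensation denominator is non-positive for sensor ",
         spec$name, ": conditions outside calibrated ambient envelope")
  }
  r_s / d
}

#' Convert a divider output voltage to sensor resistance
#'
#' The sensor is read through a series load resistor: the ADC sees
#' `v_out = v_cc * R_L / (R_L + R_s)`, so
#' `R_s = R_L * (v_cc - v_out) / v_out`. Strictly decreasing in `v_out`.
#'
#' @param v_out Measured output voltage (vectorised), must satisfy
#'   `0 < v_out < v_cc`.
#' @param spec One-row sensor spec (supplies `load_resistance_ohm`).
#' @param v_cc Supply voltage in volts; 5 V is the standard for these modules.
#' @return Sensor resistance in ohms.
#' @export
voltage_to_resistance <- function(v_out, spec, v_cc = 5) {
  if (any(v_out <= 0) || any(v_out >= v_cc)) {
    stop("invalid reading: v_out must lie strictly between 0 and v_cc")
  }
  spec$load_resistance_ohm * (v_cc - v_out) / v_out
}

#' Convert a sensor resistance to the divider output voltage
#'
#' Inverse of [voltage_to_resistance()]; used by the simulator.
#'
#' @param r_s Sensor resistance in ohms (vectorised, `>= 0`).
#' @param spec One-row sensor spec.
#' @param v_cc Supply voltage in volts.
#' @return Output voltage `v_cc * R_L / (R_L + r_s)`.
#' @export
resistance_to_voltage <- function(r_s, spec, v_cc = 5) {
  if (any(r_s < 0)) stop("resistance must be non-negative")
  v_cc * spec$load_resistance_ohm / (spec$load_resistance_ohm + r_s)
}

#' Reference per-sensor regression p-values
#'
#' A bundled reference table of per-sensor significance p-values from a prior
#' calibration of this 13-sensor array, used to exercise the pruning rule:
#' at `alpha = 0.05` it removes MQ-135 and TGS822 and retains 11 sensors.
#'
#' @return A data frame with columns `name` and `p_value`.
#' @export
reference_sensor_pvalues <- function() {
  path <- system.file("extdata", "reference_sensor_pvalues.csv",
                      package = "enosebeer")
  utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}
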