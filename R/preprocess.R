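#' Filter configuration
#'
#' @param window Trailing window length `n` of the moving average (default
#'   50 samples; the effective averaged count at each index is between 1 and
#'   `window` after gating).
#' @param gate_k Gate width as a multiple of the window's standard deviation
#'   (default 3: only values with `|p - mu| <= 3 sigma` are averaged).
#' @return A `filter_config` list.
#' @export
filter_config <- function(window = 50, gate_k = 3) {
  if (window < 1) stop("filter window must be >= 1")
  if (gate_k <= 0) stop("gate_k must be positive")
  structure(list(window = as.integer(window), gate_k = gate_k),
            class = "filter_config")
}

#' Outlier-gated trailing moving average
#'
#' A modified moving-average filter: at each index, the mean `mu` and
#' population standard deviation `sigma` of the trailing window of up to
#' `window` raw values are computed, and only the values within
#' `gate_k * sigma` of `mu` enter the unweighted average. When `sigma = 0`
#' the whole window is averaged. Output length equals input length; the
#' filter is causal, as on a real-time device.
#'
#' @param x Numeric vector (one sensor channel of one measurement).
#' @param config A [filter_config()].
#' @return Filtered numeric vector, same length as `x`.
#' @export
gated_moving_average <- function(x, config = filter_config()) {
  if (length(x) == 0) stop("series must be non-empty")
  if (anyNA(x)) stop("series contains missing values")
  .gated_ma_cpp(as.numeric(x), config$window, config$gate_k)
}

#' Discard warm-up readings
#'
#' Removes leading readings with `time_s < warmup_s` (time measured from
#' power-on). The bundled simulator already emits post-preheat time stamps,
#' so the pipeline default is no trimming; the operation is provided for
#' recordings that include the preheat transient.
#'
#' @param dataset A dataset data frame with a `time_s` column.
#' @param warmup_s Seconds to discard (`>= 0`).
#' @return The dataset without the warm-up rows.
#' @export
trim_warmup <- function(dataset, warmup_s) {
  if (warmup_s < 0) stop("warmup_s must be non-negative")
  keep <- dataset$time_s >= warmup_s
  out <- dataset[keep, , drop = FALSE]
  if (nrow(out) == 0) stop("warm-up trim removed every reading")
  if (!is.null(dataset$measurement_id)) {
    lost <- setdiff(unique(dataset$measurement_id), unique(out$measurement_id))
    if (length(lost) > 0) {
      stop("warm-up trim emptied measurement(s): ", paste(lost, collapse = ", "))
    }
  }
  rownames(out) <- NULL
  out
}

#' Fit a min-max normalizer
#'
#' Learns per-feature minimum and maximum from training data only. The state
#' is frozen once fitted; applying it to later data uses the training
#' extrema, never the new data's.
#'
#' @param features Data frame or matrix of numeric feature columns
#'   (`>= 2` rows).
#' @return A `normalizer` with named `min` and `max` vectors.
#' @export
fit_normalizer <- function(features) {
  features <- as.data.frame(features, check.names = FALSE)
  if (nrow(features) < 2) stop("need at least 2 records to fit a normalizer")
  mins <- vapply(features, min, numeric(1))
  maxs <- vapply(features, max, numeric(1))
  degenerate <- names(features)[maxs == mins]
  if (length(degenerate) > 0) {
    stop("degenerate feature(s) with max = min: ",
         paste(degenerate, collapse = ", "))
  }
  structure(list(min = mins, max = maxs), class = "normalizer")
}

#' Apply a fitted min-max normalizer
#'
#' Maps each feature to `(p - min) / (max - min)` using the fitted state.
#' Training data maps into `[0, 1]`; values outside the training range map
#' outside `[0, 1]` and are deliberately not clipped.
#'
#' @param state A fitted `normalizer`.
#' @param features Data frame/matrix whose columns all appear in the state.
#' @return Normalized features (data frame, same shape).
#' @export
apply_normalizer <- function(state, features) {
  features <- as.data.frame(features, check.names = FALSE)
  unknown <- setdiff(names(features), names(state$min))
  if (length(unknown) > 0) {
    stop("feature(s) not present in fitted normalizer: ",
         paste(unknown, collapse = ", "))
  }
  out <- features
  for (nm in names(features)) {
    out[[nm]] <- (features[[nm]] - state$min[[nm]]) /
      (state$max[[nm]] - state$min[[nm]])
  }
  out
}

#' Preprocess a dataset into a per-record feature matrix
#'
#' Runs the preprocessing chain on every sensor channel of every measurement:
#' optional warm-up trim, outlier-gated moving average on the voltage signal,
#' divider conversion to resistance, temperature/humidity compensation with
#' each record's own ambient covariates, then min-max normalization. When
#' `normalizer` is `NULL` (calibration data) the normalizer is fitted on the
#' compensated features and returned; passing a previously fitted state
#' (test data) freezes the transform to the calibration extrema.
#'
#' @param dataset A schema-conformant dataset (see [read_dataset()]).
#' @param registry Sensor registry.
#' @param filter A [filter_config()].
#' @param warmup_s Warm-up seconds to trim before filtering (default 0: the
#'   simulator pre-trims).
#' @param normalizer `NULL` to fit on this data, or a fitted `normalizer`.
#' @param v_cc Divider supply voltage used during acquisition.
#' @return A list with `features` (data frame, one column per sensor),
#'   `labels` (% v/v, `NA` where unlabeled), `sample_id`, `measurement_id`,
#'   and the fitted or supplied `normalizer`.
#' @export
preprocess_pipeline <- function(dataset, registry = sensor_registry(),
                                filter = filter_config(), warmup_s = 0,
                                normalizer = NULL, v_cc = 5) {
  validate_dataset(dataset, registry)
  if (warmup_s > 0) dataset <- trim_warmup(dataset, warmup_s)
  sensors <- registry$name
  n <- nrow(dataset)
  feat <- matrix(NA_real_, n, length(sensors))
  colnames(feat) <- sensors
  groups <- split(seq_len(n), dataset$measurement_id)
  for (idx in groups) {
    x0 <- dataset$temperature_c[idx]
    x1 <- dataset$humidity_pct[idx]
    for (i in seq_along(sensors)) {
      spec <- registry[i, , drop = FALSE]
      v <- gated_moving_average(dataset[[sensors[i]]][idx], filter)
      r <- voltage_to_resistance(v, spec, v_cc)
      feat[idx, i] <- compensate(spec, r, x0, x1)
    }
  }
  feat <- as.data.frame(feat, check.names = FALSE)
  if (is.null(normalizer)) normalizer <- fit_normalizer(feat)
  list(features = apply_normalizer(normalizer, feat),
       labels = dataset$label_abv,
       sample_id = dataset$sample_id,
       measurement_id = dataset$measurement_id,
       normalizer = normalizer)
}
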