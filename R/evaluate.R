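#' k-fold partition of record indices
#'
#' @param n Number of records.
#' @param k Fold count (`2 <= k <= n`), default 10.
#' @param seed Seed for the shuffle.
#' @param shuffle Shuffle records before folding (default `TRUE`).
#' @return List of `k` disjoint index vectors covering `1..n` whose sizes
#'   differ by at most one.
#' @export
kfold_indices <- function(n, k = 10, seed = 1, shuffle = TRUE) {
  if (k < 2) stop("k must be >= 2")
  if (k > n) stop("k must not exceed n")
  perm <- if (shuffle) {
    withr::with_seed(as.integer(seed), sample.int(n))
  } else {
    seq_len(n)
  }
  base <- n %/% k
  extra <- n %% k
  sizes <- c(rep(base + 1, extra), rep(base, k - extra))
  unname(split(perm, rep(seq_len(k), times = sizes)))
}

#' Root-mean-square error
#'
#' @param predicted,actual Equal-length numeric vectors (non-empty).
#' @return `sqrt(mean((predicted - actual)^2))`.
#' @export
rmse <- function(predicted, actual) {
  if (length(predicted) == 0) stop("empty input")
  if (length(predicted) != length(actual)) stop("length mismatch")
  sqrt(mean((predicted - actual)^2))
}

#' k-fold cross-validated RMSE
#'
#' For each fold, fits a fresh model on the complement and predicts the
#' held-out records; the reported RMSE is pooled over the concatenated
#' held-out predictions (not the mean of per-fold RMSEs).
#'
#' @param model_factory Function `(X, y) -> enose_model` (or a config list
#'   for [fit_model()]).
#' @param X Feature data frame.
#' @param y Labels.
#' @param k Fold count.
#' @param seed Seed for the fold shuffle.
#' @return List with `rmse` and the vector of held-out `predictions`
#'   (in record order).
#' @export
cross_validate <- function(model_factory, X, y, k = 10, seed = 1) {
  if (is.list(model_factory) && !is.function(model_factory)) {
    config <- model_factory
    model_factory <- function(X, y) fit_model(config, X, y)
  }
  X <- as.data.frame(X, check.names = FALSE)
  n <- nrow(X)
  folds <- kfold_indices(n, k, seed)
  preds <- rep(NA_real_, n)
  for (idx in folds) {
    model <- model_factory(X[-idx, , drop = FALSE], y[-idx])
    preds[idx] <- predict(model, X[idx, , drop = FALSE])
  }
  list(rmse = rmse(preds, y), predictions = preds)
}

#' Aggregate record-level predictions per beverage
#'
#' Arithmetic mean of the record-level predictions for each sample id,
#' pooling all bottles of a beverage.
#'
#' @param predictions Record-level predicted % v/v.
#' @param sample_ids Sample identifier per record (no missing values).
#' @return Named vector of per-beverage mean predictions, in order of first
#'   appearance.
#' @export
aggregate_by_sample <- function(predictions, sample_ids) {
  if (length(predictions) != length(sample_ids)) stop("length mismatch")
  if (anyNA(sample_ids)) stop("missing sample id")
  ids <- unique(sample_ids)
  out <- vapply(ids, function(id) mean(predictions[sample_ids == id]),
                numeric(1))
  stats::setNames(out, ids)
}

#' Percent error of a prediction against the labeled content
#'
#' @param prediction Predicted % v/v (vectorised).
#' @param labeled Labeled % v/v (`> 0`).
#' @return `|prediction - labeled| / labeled * 100`.
#' @export
percent_error <- function(prediction, labeled) {
  if (any(labeled <= 0)) stop("labeled content must be positive")
  abs(prediction - labeled) / labeled * 100
}

#' Normative labeling-tolerance check
#'
#' Brazilian brewery labeling rules allow a tolerance of +/-0.5 percent by
#' volume around the labeled alcohol content.
#'
#' @param prediction Predicted % v/v (vectorised).
#' @param labeled Labeled % v/v.
#' @param tol Tolerance in % v/v (default 0.5).
#' @return Logical: `|prediction - labeled| <= tol`.
#' @export
tolerance_check <- function(prediction, labeled, tol = 0.5) {
  stopifnot(all(is.finite(prediction)), all(is.finite(labeled)))
  abs(prediction - labeled) <= tol
}

#' Fit and evaluate the four calibration models
#'
#' Runs the full analysis stage on preprocessed matrices: sensor-significance
#' pruning on the calibration features (applied identically to all models),
#' fitting each configured model, k-fold cross-validated RMSE on the
#' calibration set, record-level test predictions, per-beverage aggregated
#' predictions with percent errors and tolerance flags, and per-model mean
#' percent error. Test RMSE is reported both record-level and on the
#' per-beverage aggregates.
#'
#' @param calib Preprocessed calibration data (list from
#'   [preprocess_pipeline()] with `features`, `labels`).
#' @param test Preprocessed test data (with `features`, `labels`,
#'   `sample_id`).
#' @param model_configs Named list of model configs
#'   (default [default_model_configs()]).
#' @param cv_k Fold count for cross-validation (default 10).
#' @param cv_seed Seed for the fold shuffle.
#' @param alpha Significance level for sensor pruning (default 0.05; set to 1
#'   to disable pruning).
#' @param tolerance Normative tolerance in % v/v (default 0.5).
#' @return An `evaluation_report` list: `significance`, per-model
#'   `rmse_validation`, `rmse_test_record`, `rmse_test_beverage`,
#'   `mean_percent_error`, a `per_beverage` data frame (model, beverage,
#'   labeled, predicted, percent_error, within_tolerance), and the configs.
#' @export
build_report <- function(calib, test, model_configs = default_model_configs(),
                         cv_k = 10, cv_seed = 1, alpha = 0.05,
                         tolerance = 0.5) {
  sig <- sensor_significance(calib$features, calib$labels, alpha)
  Xc <- calib$features[, sig$retained, drop = FALSE]
  Xt <- test$features[, sig$retained, drop = FALSE]
  labeled_by_beer <- vapply(split(test$labels, test$sample_id), function(v) v[1],
                            numeric(1))

  rows <- list()
  rmse_validation <- rmse_test_record <- rmse_test_beverage <-
    mean_pct_error <- stats::setNames(numeric(length(model_configs)),
                                      names(model_configs))
  models <- list()
  for (nm in names(model_configs)) {
    cfg <- model_configs[[nm]]
    model <- fit_model(cfg, Xc, calib$labels)
    models[[nm]] <- model
    rmse_validation[nm] <- cross_validate(cfg, Xc, calib$labels,
                                          k = cv_k, seed = cv_seed)$rmse
    pred <- predict(model, Xt)
    rmse_test_record[nm] <- rmse(pred, test$labels)
    agg <- aggregate_by_sample(pred, test$sample_id)
    lab <- labeled_by_beer[names(agg)]
    rmse_test_beverage[nm] <- rmse(agg, lab)
    pe <- percent_error(agg, lab)
    mean_pct_error[nm] <- mean(pe)
    rows[[nm]] <- data.frame(model = nm, beverage = names(agg),
                             labeled_abv = unname(lab),
                             predicted_abv = unname(agg),
                             percent_error = unname(pe),
                             within_tolerance = unname(tolerance_check(agg, lab,
                                                                       tolerance)),
                             row.names = NULL)
  }
  structure(list(significance = sig,
                 models = models,
                 rmse_validation = rmse_validation,
                 rmse_test_record = rmse_test_record,
                 rmse_test_beverage = rmse_test_beverage,
                 mean_percent_error = mean_pct_error,
                 per_beverage = do.call(rbind, c(rows, make.row.names = FALSE)),
                 cv = list(k = cv_k, seed = cv_seed),
                 alpha = alpha, tolerance = tolerance),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("e-nose evaluation report\n")
  cat(sprintf("sensors retained: %d of %d (alpha = %g)\n",
              length(x$significance$retained),
              length(x$significance$p_values), x$alpha))
  tab <- data.frame(rmse_validation = round(x$rmse_validation, 4),
                    rmse_test = round(x$rmse_test_record, 4),
                    mean_pct_error = round(x$mean_percent_error, 2))
  print(tab)
  invisible(x)
}

#' Write an evaluation report to disk
#'
#' Emits two CSV tables (per-model RMSE summary; per-model-and-beverage
#' percent errors with the per-model average) and one JSON bundle embedding
#' the configs, seeds and a config hash for provenance.
#'
#' @param report An `evaluation_report`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rmse_tab <- data.frame(method = names(report$rmse_validation),
                         rmse_validation_kfold = unname(report$rmse_validation),
                         rmse_test = unname(report$rmse_test_record),
                         rmse_test_beverage = unname(report$rmse_test_beverage),
                         row.names = NULL)
  rmse_path <- file.path(dir, "rmse_summary.csv")
  utils::write.csv(rmse_tab, rmse_path, row.names = FALSE)

  wide <- stats::reshape(report$per_beverage[, c("model", "beverage",
                                                 "percent_error")],
                         idvar = "model", timevar = "beverage",
                         direction = "wide")
  names(wide) <- sub("^percent_error\\.", "", names(wide))
  wide$Average <- unname(report$mean_percent_error[wide$model])
  pct_path <- file.path(dir, "percent_error.csv")
  utils::write.csv(wide, pct_path, row.names = FALSE)

  bundle <- list(
    config_hash = config_hash(list(cv = report$cv, alpha = report$alpha,
                                   tolerance = report$tolerance,
                                   sensors = report$significance$retained)),
    alpha = report$alpha, tolerance = report$tolerance, cv = report$cv,
    significance = list(p_values = as.list(report$significance$p_values),
                        retained = report$significance$retained,
                        removed = report$significance$removed),
    rmse_validation = as.list(report$rmse_validation),
    rmse_test_record = as.list(report$rmse_test_record),
    rmse_test_beverage = as.list(report$rmse_test_beverage),
    mean_percent_error = as.list(report$mean_percent_error),
    per_beverage = report$per_beverage)
  json_path <- file.path(dir, "report.json")
  jsonlite::write_json(bundle, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(rmse_path, pct_path, json_path))
}

# Internal: md5 of the canonical JSON serialization of a config object.
config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  jsonlite::write_json(x, f, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(f))
}
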