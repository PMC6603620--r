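# Internal: coerce features to a numeric matrix with original column names.
as_feature_matrix <- function(X) {
  X <- as.data.frame(X, check.names = FALSE)
  if (!all(vapply(X, is.numeric, logical(1)))) {
    stop("all feature columns must be numeric")
  }
  as.matrix(X)
}

# Internal: OLS with intercept via lm on sanitized names; returns coefficients
# (original names), fit statistics and the per-coefficient t-test p-values.
#
# Exactly dependent columns (QR pivot ratio below ~1e-12) are a hard error.
# Columns that are only numerically near-dependent (possible on noise-free
# synthetic data, where all channels are smooth functions of one latent
# concentration) are aliased by lm's pivoted QR; such a column contributes
# nothing given the others, so it enters the result with coefficient 0 and
# partial p-value 1 rather than aborting the fit.
ols_fit <- function(X, y) {
  X <- as_feature_matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  if (n <= p + 1) stop("need more records than predictors + 1")
  M <- cbind(`(Intercept)` = 1, X)
  if (qr(M, tol = 1e-12)$rank < ncol(M)) {
    piv <- qr(M, tol = 1e-12)
    dep <- colnames(M)[piv$pivot[-seq_len(piv$rank)]]
    stop("rank-deficient feature matrix; linearly dependent column(s): ",
         paste(setdiff(dep, "(Intercept)"), collapse = ", "))
  }
  dat <- as.data.frame(X)
  names(dat) <- paste0("x", seq_len(p))
  dat$.y <- y
  fit <- stats::lm(.y ~ ., data = dat)
  aliased <- names(stats::coef(fit))[is.na(stats::coef(fit))]
  if (length(aliased) > 0) {
    keep <- setdiff(names(dat), c(aliased, ".y"))
    fit <- stats::lm(.y ~ ., data = dat[, c(keep, ".y"), drop = FALSE])
  }
  sm <- summary(fit)
  coefs <- stats::setNames(rep(0, p), paste0("x", seq_len(p)))
  pvals <- stats::setNames(rep(1, p), paste0("x", seq_len(p)))
  est <- stats::coef(fit)[-1]
  coefs[names(est)] <- est
  pvals[rownames(sm$coefficients)[-1]] <- sm$coefficients[-1, 4]
  r2 <- sm$r.squared
  list(intercept = unname(stats::coef(fit)[1]),
       coefficients = stats::setNames(unname(coefs), colnames(X)),
       p_values = stats::setNames(unname(pvals), colnames(X)),
       r_squared = r2,
       r_squared_adj = 1 - (1 - r2) * (n - 1) / (n - p - 1),
       sigma = sm$sigma, n = n, p = p)
}

#' Per-sensor significance test
#'
#' Fits ordinary least squares of the labels on all sensor features plus an
#' intercept and tests each sensor's coefficient with the standard t-test
#' (equivalent to the 1-degree-of-freedom partial F-test). Sensors whose
#' p-value exceeds `alpha` do not contribute significantly and are marked for
#' removal; at the default 95% confidence level the bundled reference
#' p-values remove MQ-135 and TGS822, retaining 11 sensors.
#'
#' @param X Feature matrix/data frame (one column per sensor).
#' @param y Labels in % v/v.
#' @param alpha Significance level (default 0.05).
#' @return A `significance_report`: `p_values` (named), `alpha`, `retained`
#'   and `removed` sensor-name sets.
#' @export
sensor_significance <- function(X, y, alpha = 0.05) {
  fit <- ols_fit(X, y)
  significance_report(fit$p_values, alpha)
}

#' Build a significance report from p-values
#'
#' @param p_values Named per-sensor p-values in `[0, 1]`.
#' @param alpha Significance level; a sensor is removed iff `p > alpha`.
#' @return A `significance_report`.
#' @export
significance_report <- function(p_values, alpha = 0.05) {
  stopifnot(!is.null(names(p_values)), all(p_values >= 0 & p_values <= 1))
  removed <- names(p_values)[p_values > alpha]
  structure(list(p_values = p_values, alpha = alpha,
                 retained = setdiff(names(p_values), removed),
                 removed = removed),
            class = "significance_report")
}

#' @export
print.significance_report <- function(x, ...) {
  cat(sprintf("Sensor significance at alpha = %g: %d retained, %d removed\n",
              x$alpha, length(x$retained), length(x$removed)))
  if (length(x$removed) > 0) {
    cat("removed:", paste(x$removed, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Multiple linear regression calibration model
#'
#' @param X Feature matrix/data frame.
#' @param y Labels in % v/v.
#' @return An `enose_model` of kind MLR with intercept, coefficients,
#'   `r_squared` and `r_squared_adj`.
#' @export
fit_mlr <- function(X, y) {
  fit <- ols_fit(X, y)
  structure(list(kind = "MLR", sensors = names(fit$coefficients),
                 intercept = fit$intercept, coefficients = fit$coefficients,
                 r_squared = fit$r_squared, r_squared_adj = fit$r_squared_adj),
            class = c("enose_mlr", "enose_model"))
}

#' Multiple nonlinear (log-transformed) regression calibration model
#'
#' Applies `x -> log(x + log_offset)` to every predictor and fits ordinary
#' least squares on the transformed matrix; prediction applies the stored
#' transform. Motivated by the saturating sensor response at high alcohol
#' contents. `transform = "response"` instead fits `log(y + log_offset)` on
#' the raw predictors and back-transforms predictions.
#'
#' @param X Feature matrix/data frame.
#' @param y Labels in % v/v.
#' @param log_offset Positive constant keeping the log argument positive.
#'   The default 1 is of the order of the normalized feature range, giving a
#'   gently saturating transform on `[0, 1]` whose domain stays safe for
#'   test features below the calibration minimum (normalized values are not
#'   clipped and may go negative).
#' @param transform `"predictors"` (default) or `"response"`.
#' @return An `enose_model` of kind MNLR.
#' @export
fit_mnlr <- function(X, y, log_offset = 1,
                     transform = c("predictors", "response")) {
  transform <- match.arg(transform)
  if (log_offset <= 0) stop("log_offset must be positive")
  X <- as_feature_matrix(X)
  if (transform == "predictors") {
    if (any(X <= -log_offset)) {
      stop("predictor value <= -log_offset: log transform undefined")
    }
    fit <- ols_fit(log(X + log_offset), y)
  } else {
    if (any(y <= -log_offset)) stop("label <= -log_offset: log transform undefined")
    fit <- ols_fit(X, log(y + log_offset))
  }
  structure(list(kind = "MNLR", sensors = names(fit$coefficients),
                 intercept = fit$intercept, coefficients = fit$coefficients,
                 log_offset = log_offset, transform = transform,
                 r_squared = fit$r_squared, r_squared_adj = fit$r_squared_adj),
            class = c("enose_mnlr", "enose_model"))
}

# Internal: minimum-norm least-squares solve via SVD with a relative rank
# tolerance; ties the output weights to the smallest-norm solution.
min_norm_solve <- function(H, y, tol = 1e-10) {
  sv <- svd(H)
  keep <- sv$d > tol * sv$d[1]
  if (!any(keep)) stop("hidden matrix is numerically zero")
  sv$v[, keep, drop = FALSE] %*%
    ((crossprod(sv$u[, keep, drop = FALSE], y)) / sv$d[keep])
}

elm_activation <- function(name) {
  switch(name,
         purelin = identity,
         sig = function(z) 1 / (1 + exp(-z)),
         tanh = tanh,
         stop("unknown activation function: ", name))
}

#' Extreme learning machine calibration model
#'
#' A single-hidden-layer feedforward network whose input weights and hidden
#' biases are drawn once from Uniform(-1, 1) under `seed` and frozen; the
#' output weights are the minimum-norm least-squares solution
#' (Moore-Penrose pseudoinverse, relative rank tolerance 1e-10) of
#' `H beta = y` with hidden matrix `H = g(X W + b)`. The default activation
#' is `"purelin"` (identity), making the model prediction-equivalent to MLR
#' whenever the hidden matrix spans the affine hull of the features.
#'
#' @param X Feature matrix/data frame.
#' @param y Labels in % v/v.
#' @param nhid Hidden-unit count (default 15).
#' @param actfun Activation: `"purelin"`, `"sig"` or `"tanh"`.
#' @param seed Integer seed for the random input weights.
#' @return An `enose_model` of kind ELM.
#' @export
fit_elm <- function(X, y, nhid = 15, actfun = "purelin", seed = 1) {
  if (nhid < 1) stop("nhid must be >= 1")
  X <- as_feature_matrix(X)
  if (nrow(X) < 2) stop("need at least 2 records")
  g <- elm_activation(actfun)
  p <- ncol(X)
  wb <- withr::with_seed(as.integer(seed), {
    list(W = matrix(stats::runif(p * nhid, -1, 1), p, nhid),
         b = stats::runif(nhid, -1, 1))
  })
  H <- g(sweep(X %*% wb$W, 2, wb$b, "+"))
  beta <- min_norm_solve(H, y)
  structure(list(kind = "ELM", sensors = colnames(X), nhid = nhid,
                 actfun = actfun, seed = as.integer(seed),
                 input_weights = wb$W, biases = wb$b,
                 output_weights = as.numeric(beta)),
            class = c("enose_elm", "enose_model"))
}

#' Random forest calibration model
#'
#' An ensemble of `ntree` regression trees, each grown on a bootstrap
#' resample of size n, choosing the best variance-reducing split among `mtry`
#' randomly selected predictors per node, without pruning (terminal nodes of
#' at least `min_node` records, no depth cap). Backed by the `ranger`
#' engine; predictions are the mean over trees.
#'
#' @param X Feature matrix/data frame.
#' @param y Labels in % v/v.
#' @param ntree Number of trees (default 500).
#' @param mtry Predictors sampled per split (default 4).
#' @param seed Integer seed.
#' @param min_node Minimum node size to split (default 5).
#' @param replace Bootstrap with replacement (default `TRUE`).
#' @param sample_fraction Fraction of records per tree (default 1).
#' @return An `enose_model` of kind RF.
#' @export
fit_rf <- function(X, y, ntree = 500, mtry = 4, seed = 1,
                   min_node = 5, replace = TRUE, sample_fraction = 1) {
  X <- as.data.frame(as_feature_matrix(X), check.names = FALSE)
  if (ntree < 1) stop("ntree must be >= 1")
  if (mtry < 1 || mtry > ncol(X)) {
    stop("mtry must lie between 1 and the number of predictors (",
         ncol(X), ")")
  }
  if (nrow(X) < 2) stop("need at least 2 records")
  fit <- ranger::ranger(x = X, y = y, num.trees = ntree, mtry = mtry,
                        min.node.size = min_node, replace = replace,
                        sample.fraction = sample_fraction,
                        seed = as.integer(seed), num.threads = 1,
                        verbose = FALSE)
  structure(list(kind = "RF", sensors = colnames(X), ntree = ntree,
                 mtry = mtry, seed = as.integer(seed), forest = fit),
            class = c("enose_rf", "enose_model"))
}

# Internal: newdata validation shared by all model kinds. Columns bind by
# name, never by position.
model_newdata <- function(object, newdata) {
  newdata <- as.data.frame(newdata, check.names = FALSE)
  missing <- setdiff(object$sensors, names(newdata))
  if (length(missing) > 0) {
    stop("newdata is missing model feature(s): ",
         paste(missing, collapse = ", "))
  }
  as_feature_matrix(newdata[, object$sensors, drop = FALSE])
}

#' Predict ethanol content per record
#'
#' Uniform prediction contract over the four model kinds: validates that the
#' model's retained sensors are present (binding by name, so column order is
#' irrelevant) and applies the model's stored transforms.
#'
#' @param object A fitted `enose_model`.
#' @param newdata Feature data frame containing the model's sensors.
#' @param ... Unused.
#' @return Numeric vector of predicted % v/v, one per record.
#' @name predict.enose_model
NULL

#' @rdname predict.enose_model
#' @export
predict.enose_mlr <- function(object, newdata, ...) {
  X <- model_newdata(object, newdata)
  as.numeric(object$intercept + X %*% object$coefficients)
}

#' @rdname predict.enose_model
#' @export
predict.enose_mnlr <- function(object, newdata, ...) {
  X <- model_newdata(object, newdata)
  if (object$transform == "predictors") {
    if (any(X <= -object$log_offset)) {
      stop("predictor value <= -log_offset: log transform undefined")
    }
    as.numeric(object$intercept + log(X + object$log_offset) %*% object$coefficients)
  } else {
    exp(as.numeric(object$intercept + X %*% object$coefficients)) - object$log_offset
  }
}

#' @rdname predict.enose_model
#' @export
predict.enose_elm <- function(object, newdata, ...) {
  X <- model_newdata(object, newdata)
  g <- elm_activation(object$actfun)
  H <- g(sweep(X %*% object$input_weights, 2, object$biases, "+"))
  as.numeric(H %*% object$output_weights)
}

#' @rdname predict.enose_model
#' @export
predict.enose_rf <- function(object, newdata, ...) {
  X <- as.data.frame(model_newdata(object, newdata), check.names = FALSE)
  as.numeric(stats::predict(object$forest, data = X,
                            num.threads = 1, verbose = FALSE)$predictions)
}

#' Default model configurations
#'
#' The four calibration regressors with their standard hyperparameters:
#' ELM with 15 identity-activation hidden units, RF with 500 trees and
#' `mtry = 4`, MNLR with a log-predictor transform.
#'
#' @param seed Base seed for the stochastic learners (ELM, RF).
#' @return Named list of config lists understood by [fit_model()].
#' @export
default_model_configs <- function(seed = 1) {
  list(MLR  = list(kind = "MLR"),
       MNLR = list(kind = "MNLR", log_offset = 1, transform = "predictors"),
       ELM  = list(kind = "ELM", nhid = 15, actfun = "purelin", seed = seed),
       RF   = list(kind = "RF", ntree = 500, mtry = 4, seed = seed))
}

#' Fit a calibration model from a config
#'
#' @param config A list with a `kind` in `{"MLR", "MNLR", "ELM", "RF"}` plus
#'   that kind's hyperparameters (see [default_model_configs()]).
#' @param X Feature matrix/data frame.
#' @param y Labels.
#' @return A fitted `enose_model`.
#' @export
fit_model <- function(config, X, y) {
  switch(config$kind,
    MLR  = fit_mlr(X, y),
    MNLR = fit_mnlr(X, y,
                    log_offset = config$log_offset %||% 1,
                    transform = config$transform %||% "predictors"),
    ELM  = fit_elm(X, y, nhid = config$nhid %||% 15,
                   actfun = config$actfun %||% "purelin",
                   seed = config$seed %||% 1),
    RF   = fit_rf(X, y, ntree = config$ntree %||% 500,
                  mtry = config$mtry %||% 4,
                  seed = config$seed %||% 1),
    stop("unknown model kind: ", config$kind))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
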