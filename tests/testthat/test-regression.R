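test_that("sensor significance flags a perfect predictor and partitions sensors", {
  prob <- withr::with_seed(31, {
    X <- data.frame(good = runif(60), junk1 = rnorm(60), junk2 = rnorm(60))
    list(X = X, y = 2 * X$good + 1)
  })
  rep <- sensor_significance(prob$X, prob$y)
  expect_lt(rep$p_values[["good"]], 1e-10)
  expect_setequal(c(rep$retained, rep$removed), names(prob$X))
  expect_length(intersect(rep$retained, rep$removed), 0)
  expect_true(all(rep$p_values[rep$removed] > rep$alpha))
  expect_true(all(rep$p_values[rep$retained] <= rep$alpha))
})

test_that("rank-deficient feature matrices raise a collinearity error naming columns", {
  X <- withr::with_seed(32, data.frame(a = rnorm(30), b = rnorm(30)))
  X$c <- X$a + X$b
  y <- rnorm(30)
  expect_error(sensor_significance(X, y), "dependent column\\(s\\): c")
  expect_error(fit_mlr(X, y), "rank-deficient")
})

test_that("per-sensor p-values agree with a permutation oracle on a small design", {
  prob <- withr::with_seed(33, {
    n <- 30
    X <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
    y <- 0.45 * X$x1 + 0.25 * X$x2 + rnorm(n)
    list(X = X, y = y)
  })
  obs <- sensor_significance(prob$X, prob$y)$p_values

  # permutation oracle: permute y, recompute each coefficient's t statistic
  M <- cbind(1, as.matrix(prob$X))
  qrM <- qr(M)
  xtx_inv_diag <- diag(chol2inv(qr.R(qrM)))
  tstats <- function(yy) {
    cf <- qr.coef(qrM, yy)
    res <- yy - M %*% cf
    s2 <- sum(res^2) / (nrow(M) - ncol(M))
    (cf / sqrt(s2 * xtx_inv_diag))[-1]
  }
  t_obs <- abs(tstats(prob$y))
  nperm <- 10000
  exceed <- matrix(FALSE, nperm, 3)
  withr::with_seed(34, {
    for (b in seq_len(nperm)) {
      exceed[b, ] <- abs(tstats(sample(prob$y))) >= t_obs
    }
  })
  perm_p <- colMeans(exceed)
  expect_equal(unname(obs), unname(perm_p), tolerance = 0.03)
})

test_that("MLR recovers exact affine data and matches the normal equations", {
  prob <- affine_problem(n = 50, p = 4, seed = 41)
  m <- fit_mlr(prob$X, prob$y)
  expect_equal(unname(m$coefficients), prob$beta, tolerance = 1e-9)
  expect_equal(m$intercept, prob$intercept, tolerance = 1e-9)
  expect_equal(m$r_squared, 1, tolerance = 1e-12)
  expect_lt(max(abs(predict(m, prob$X) - prob$y)), 1e-9)

  noisy <- affine_problem(n = 80, p = 3, seed = 42, noise_sd = 0.5)
  m2 <- fit_mlr(noisy$X, noisy$y)
  # independent normal-equations solve
  M <- cbind(1, as.matrix(noisy$X))
  beta_ne <- solve(t(M) %*% M, t(M) %*% noisy$y)
  expect_equal(c(m2$intercept, unname(m2$coefficients)), as.numeric(beta_ne),
               tolerance = 1e-8)
  # adjusted R2 definition
  n <- 80; p <- 3
  expect_equal(m2$r_squared_adj,
               1 - (1 - m2$r_squared) * (n - 1) / (n - p - 1))
})

test_that("single-predictor MLR reduces to the closed-form slope", {
  d <- withr::with_seed(43, data.frame(x = runif(40)))
  y <- withr::with_seed(44, 3 * d$x + rnorm(40))
  m <- fit_mlr(d, y)
  slope <- stats::cov(d$x, y) / stats::var(d$x)
  expect_equal(unname(m$coefficients["x"]), slope, tolerance = 1e-10)
  expect_equal(m$intercept, mean(y) - slope * mean(d$x), tolerance = 1e-10)
})

test_that("MNLR is MLR on log-transformed predictors and fits log-true data exactly", {
  X <- withr::with_seed(45, data.frame(a = runif(60, 0, 2), b = runif(60, 0, 2)))
  off <- 0.1
  y <- 2 + 3 * log(X$a + off) - 1.5 * log(X$b + off)
  m <- fit_mnlr(X, y, log_offset = off)
  expect_equal(m$r_squared, 1, tolerance = 1e-12)
  expect_lt(max(abs(predict(m, X) - y)), 1e-9)

  ref <- fit_mlr(log(X + off), y)
  expect_equal(m$coefficients, ref$coefficients)
  expect_equal(m$intercept, ref$intercept)

  expect_error(fit_mnlr(data.frame(a = c(-0.2, 1, 2, 3)), c(1, 2, 3, 4),
                        log_offset = 0.1), "log transform")
  expect_error(fit_mnlr(X, y, log_offset = 0), "positive")
})

test_that("MNLR beats MLR on data with a saturating log-shaped response", {
  prob <- withr::with_seed(46, {
    x <- runif(200, 0.05, 1)
    X <- data.frame(s = x)
    y <- 4 * log(x + 0.1) + rnorm(200, 0, 0.05)
    list(X = X, y = y)
  })
  rmse_lin <- rmse(predict(fit_mlr(prob$X, prob$y), prob$X), prob$y)
  rmse_log <- rmse(predict(fit_mnlr(prob$X, prob$y, log_offset = 0.1), prob$X),
                   prob$y)
  expect_lte(rmse_log, rmse_lin)
})

test_that("ELM output weights equal an independent minimum-norm solve", {
  prob <- affine_problem(n = 20, p = 3, seed = 51, noise_sd = 0.3)
  m <- fit_elm(prob$X, prob$y, nhid = 6, seed = 99)
  H <- as.matrix(prob$X) %*% m$input_weights
  H <- sweep(H, 2, m$biases, "+")
  beta_oracle <- MASS::ginv(H) %*% prob$y
  expect_equal(m$output_weights, as.numeric(beta_oracle), tolerance = 1e-8)
})

test_that("identity-activation ELM spans the affine hull and is seed-stable", {
  prob <- affine_problem(n = 60, p = 4, seed = 52)
  m <- fit_elm(prob$X, prob$y, nhid = 15, seed = 1)
  expect_lt(rmse(predict(m, prob$X), prob$y), 1e-8)

  m_same <- fit_elm(prob$X, prob$y, nhid = 15, seed = 1)
  expect_identical(predict(m, prob$X), predict(m_same, prob$X))

  # identity activation: predictions depend only on the feature column space,
  # so even different random weights give the same predictions
  noisy <- affine_problem(n = 60, p = 4, seed = 53, noise_sd = 0.4)
  newX <- affine_problem(n = 25, p = 4, seed = 54)$X
  p1 <- predict(fit_elm(noisy$X, noisy$y, nhid = 15, seed = 7), newX)
  p2 <- predict(fit_elm(noisy$X, noisy$y, nhid = 15, seed = 1234), newX)
  expect_equal(p1, p2, tolerance = 1e-8)
  # and equal MLR on the same features
  expect_equal(p1, predict(fit_mlr(noisy$X, noisy$y), newX), tolerance = 1e-8)

  expect_error(fit_elm(prob$X, prob$y, nhid = 0), ">= 1")
})

test_that("random forest respects label bounds and degenerate labels", {
  prob <- affine_problem(n = 40, p = 3, seed = 61, noise_sd = 1)
  m <- fit_rf(prob$X, prob$y, ntree = 50, mtry = 2, seed = 1)
  pred <- predict(m, prob$X)
  expect_true(all(pred >= min(prob$y) & pred <= max(prob$y)))

  const <- fit_rf(prob$X, rep(4.2, 40), ntree = 20, mtry = 2, seed = 1)
  expect_equal(predict(const, prob$X), rep(4.2, 40))

  expect_error(fit_rf(prob$X, prob$y, mtry = 10), "mtry")
})

test_that("a deterministic single tree reproduces the exhaustive-split CART oracle", {
  fx <- cart_fixture()
  m <- fit_rf(fx$X, fx$y, ntree = 1, mtry = ncol(fx$X), seed = 5,
              min_node = 5, replace = FALSE, sample_fraction = 1)
  expect_equal(predict(m, fx$X), cart_oracle_predict(fx$X, fx$y, min_split = 5),
               tolerance = 1e-12)
})

test_that("tree partitions are invariant to strictly monotone feature transforms", {
  fx <- cart_fixture()
  m1 <- fit_rf(fx$X, fx$y, ntree = 1, mtry = 2, seed = 5,
               min_node = 5, replace = FALSE, sample_fraction = 1)
  Xt <- data.frame(x1 = exp(fx$X$x1 / 4), x2 = fx$X$x2^3)
  m2 <- fit_rf(Xt, fx$y, ntree = 1, mtry = 2, seed = 5,
               min_node = 5, replace = FALSE, sample_fraction = 1)
  expect_equal(predict(m1, fx$X), predict(m2, Xt), tolerance = 1e-12)
  expect_equal(cart_oracle_predict(Xt, fx$y, 5), cart_oracle_predict(fx$X, fx$y, 5))
})

test_that("MLR estimates converge to truth as noise shrinks and n grows", {
  err <- function(n, noise) {
    prob <- affine_problem(n = n, p = 3, seed = 71, noise_sd = noise)
    max(abs(unname(fit_mlr(prob$X, prob$y)$coefficients) - prob$beta))
  }
  expect_lt(err(200, 0.01), err(200, 1))
  expect_lt(err(5000, 0.3), err(50, 0.3))
  expect_lt(err(5000, 0.001), 0.01)
})

test_that("prediction binds features by name, not position", {
  prob <- affine_problem(n = 30, p = 3, seed = 81, noise_sd = 0.1)
  models <- list(fit_mlr(prob$X, prob$y),
                 fit_mnlr(prob$X, prob$y),
                 fit_elm(prob$X, prob$y, nhid = 8, seed = 2),
                 fit_rf(prob$X, prob$y, ntree = 20, mtry = 2, seed = 2))
  shuffled <- prob$X[, c("s3", "s1", "s2")]
  extra <- cbind(prob$X, irrelevant = 1)
  for (m in models) {
    expect_equal(predict(m, shuffled), predict(m, prob$X))
    expect_equal(predict(m, extra), predict(m, prob$X))
    expect_error(predict(m, prob$X[, 1:2]), "missing model feature")
  }
})

test_that("fit_model dispatches on the configured kind", {
  prob <- affine_problem(n = 30, p = 3, seed = 82, noise_sd = 0.1)
  cfgs <- default_model_configs(seed = 3)
  cfgs$RF$mtry <- 2
  for (nm in names(cfgs)) {
    m <- fit_model(cfgs[[nm]], prob$X, prob$y)
    expect_s3_class(m, "enose_model")
    expect_equal(m$kind, nm)
    expect_true(all(is.finite(predict(m, prob$X))))
  }
  expect_error(fit_model(list(kind = "SVM"), prob$X, prob$y), "unknown model kind")
})
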