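test_that("k-fold partitions are balanced, disjoint and exhaustive", {
  folds <- kfold_indices(10, 10, seed = 1)
  expect_length(folds, 10)
  expect_true(all(lengths(folds) == 1))

  folds <- kfold_indices(43200, 10, seed = 1)
  expect_true(all(lengths(folds) == 4320))

  withr::with_seed(90, {
    for (case in 1:100) {
      n <- sample(10:200, 1)
      k <- sample(2:min(n, 12), 1)
      f <- kfold_indices(n, k, seed = case)
      all_idx <- unlist(f)
      expect_equal(sort(all_idx), 1:n)
      expect_equal(length(all_idx), length(unique(all_idx)))
      expect_lte(diff(range(lengths(f))), 1)
    }
  })
  expect_error(kfold_indices(5, 6), "exceed")
  expect_error(kfold_indices(5, 1), ">= 2")
})

test_that("cross-validation pools held-out predictions and matches a hand loop", {
  prob <- affine_problem(n = 50, p = 3, seed = 91, noise_sd = 0.4)
  cv <- cross_validate(function(X, y) fit_mlr(X, y), prob$X, prob$y,
                       k = 5, seed = 17)

  # independent fold-by-fold reimplementation with the same partition
  folds <- kfold_indices(50, 5, seed = 17)
  preds <- rep(NA_real_, 50)
  for (idx in folds) {
    m <- fit_mlr(prob$X[-idx, ], prob$y[-idx])
    preds[idx] <- predict(m, prob$X[idx, ])
  }
  expect_equal(cv$predictions, preds, tolerance = 1e-12)
  expect_equal(cv$rmse, sqrt(mean((preds - prob$y)^2)), tolerance = 1e-12)
  # pooled RMSE, not the mean of per-fold RMSEs
  per_fold <- vapply(folds, function(idx)
    sqrt(mean((preds[idx] - prob$y[idx])^2)), numeric(1))
  expect_false(isTRUE(all.equal(cv$rmse, mean(per_fold))))

  # deterministic given the same seed; config-list factories work too
  cv2 <- cross_validate(list(kind = "MLR"), prob$X, prob$y, k = 5, seed = 17)
  expect_identical(cv$rmse, cv2$rmse)

  exact <- affine_problem(n = 40, p = 3, seed = 92)
  expect_lt(cross_validate(list(kind = "MLR"), exact$X, exact$y,
                           k = 5, seed = 1)$rmse, 1e-8)
})

test_that("rmse follows its definition and dominates the mean error", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(0.3, -0.4), c(0, 0)), sqrt(0.125))
  withr::with_seed(93, {
    for (i in 1:20) {
      p <- rnorm(30); a <- rnorm(30)
      expect_gte(rmse(p, a) + 1e-12, abs(mean(p - a)))
    }
  })
  expect_error(rmse(numeric(0), numeric(0)), "empty")
  expect_error(rmse(1:3, 1:4), "mismatch")
})

test_that("per-beverage aggregation is the mean over all records of both bottles", {
  expect_equal(aggregate_by_sample(rep(5, 8), rep("C5", 8)), c(C5 = 5))
  expect_equal(aggregate_by_sample(c(rep(4, 6), rep(5, 6)),
                                   rep("C4.5", 12)), c(C4.5 = 4.5))

  withr::with_seed(94, {
    pred <- rnorm(20, 5)
    ids <- sample(c("a", "b", "c"), 20, replace = TRUE)
    agg <- aggregate_by_sample(pred, ids)
    for (id in unique(ids)) {
      expect_equal(unname(agg[id]), mean(pred[ids == id]))
    }
  })
  expect_error(aggregate_by_sample(1:3, c("a", NA, "b")), "missing sample id")
  expect_error(aggregate_by_sample(1:3, c("a", "b")), "mismatch")
})

test_that("percent error and the normative tolerance follow their definitions", {
  expect_equal(percent_error(4.5, 4.5), 0)
  expect_equal(percent_error(4.5, 4.0), 12.5)
  expect_equal(percent_error(3.5, 4.0), percent_error(4.5, 4.0))
  expect_error(percent_error(4, 0), "positive")

  expect_true(tolerance_check(5.0, 4.5))    # boundary counts as within
  expect_true(tolerance_check(4.5, 4.5))
  expect_false(tolerance_check(6.0, 5.4))
  expect_equal(tolerance_check(c(4.4, 5.1), c(4, 4)), c(TRUE, FALSE))
})

test_that("the evaluation report is internally consistent on a zero-noise run", {
  reg <- sensor_registry()
  design <- short_design(30)
  cal <- simulate_calibration_dataset(design, simulation_config(seed = 95,
                                                                noise_sd = 0), reg)
  tst <- simulate_test_dataset(neutral_panel(), 2, design,
                               simulation_config(seed = 96, noise_sd = 0), reg)
  pc <- preprocess_pipeline(cal, reg)
  pt <- preprocess_pipeline(tst, reg, normalizer = pc$normalizer)
  cfgs <- default_model_configs(seed = 2)
  cfgs$RF$ntree <- 100
  report <- build_report(pc, pt, model_configs = cfgs, cv_k = 5, cv_seed = 3)

  # with no noise and no VOC excess every linear-family model hits every beer
  for (mk in c("MLR", "ELM")) {
    sub <- report$per_beverage[report$per_beverage$model == mk, ]
    expect_true(all(sub$within_tolerance))
    expect_true(all(abs(sub$predicted_abv - sub$labeled_abv) < 0.1))
  }
  # mean percent error equals the row mean recomputed independently
  for (mk in names(cfgs)) {
    sub <- report$per_beverage[report$per_beverage$model == mk, ]
    expect_equal(unname(report$mean_percent_error[mk]), mean(sub$percent_error))
    expect_equal(sub$percent_error,
                 abs(sub$predicted_abv - sub$labeled_abv) / sub$labeled_abv * 100)
    expect_equal(unname(report$rmse_test_beverage[mk]),
                 rmse(sub$predicted_abv, sub$labeled_abv))
  }
})

test_that("report serialization round-trips and embeds provenance", {
  reg <- sensor_registry()
  design <- short_design(15)
  cal <- simulate_calibration_dataset(design, simulation_config(seed = 97), reg)
  tst <- simulate_test_dataset(beverage_panel(), 1, design,
                               simulation_config(seed = 98), reg)
  pc <- preprocess_pipeline(cal, reg)
  pt <- preprocess_pipeline(tst, reg, normalizer = pc$normalizer)
  cfgs <- default_model_configs(seed = 2)
  cfgs$RF$ntree <- 50
  report <- build_report(pc, pt, model_configs = cfgs, cv_k = 4, cv_seed = 3)

  dir <- tempfile("report")
  paths <- write_report(report, dir)
  expect_true(all(file.exists(paths)))
  tab <- read.csv(file.path(dir, "rmse_summary.csv"))
  expect_equal(tab$rmse_validation_kfold, unname(report$rmse_validation))
  expect_equal(tab$rmse_test, unname(report$rmse_test_record))

  bundle <- jsonlite::read_json(file.path(dir, "report.json"),
                                simplifyVector = TRUE)
  expect_equal(unlist(bundle$mean_percent_error),
               report$mean_percent_error, tolerance = 1e-12)
  expect_match(bundle$config_hash, "^[0-9a-f]{32}$")
  pct <- read.csv(file.path(dir, "percent_error.csv"), check.names = FALSE)
  expect_setequal(pct$model, names(cfgs))
  expect_equal(pct$Average[pct$model == "MLR"],
               unname(report$mean_percent_error["MLR"]))
})
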