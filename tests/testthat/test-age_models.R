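test_that("mse and r_squared match their defining formulas", {
  expect_equal(mse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(mse(c(2, 3), c(3, 3)), 0.5)
  expect_error(mse(1:3, 1:2), "length")

  expect_equal(r_squared(c(2, 3, 5), c(2, 3, 5)), 1)
  expect_equal(r_squared(rep(mean(c(2, 3, 5)), 3), c(2, 3, 5)), 0)
  # hand computation: 1 - 1/(14/3) = 11/14
  expect_equal(r_squared(c(2, 3, 4), c(2, 3, 5)), 11 / 14, tolerance = 1e-12)
  expect_error(r_squared(c(1, 2), c(3, 3)), "denominator")

  # brute-force recomputation on random vectors
  withr::with_seed(8L, {
    for (i in 1:20) {
      true <- rnorm(15); pred <- true + rnorm(15, sd = 0.5)
      expect_equal(mse(pred, true), sum((pred - true)^2) / 15, tolerance = 1e-12)
      expect_equal(r_squared(pred, true),
                   1 - sum((pred - true)^2) / sum((true - mean(true))^2),
                   tolerance = 1e-12)
    }
  })
})

test_that("the printed r-squared variant divides by spread of predictions", {
  pred <- c(2, 3, 4); true <- c(2, 3, 5)
  expect_equal(r_squared(pred, true, form = "printed"),
               1 - 1 / sum((pred - mean(true))^2), tolerance = 1e-12)
})

test_that("a noiseless linear age signal is fit nearly perfectly by elastic net", {
  t <- make_signal_table(signal = c(weight = 3, rb1 = 5), noise_sd = 0.01)
  gs <- grid_search_train(model_spec("elastic_net", seed = 1L), t)
  expect_gt(gs$cv$r2, 0.99)
  expect_lt(gs$cv$mse, 0.01)
})

test_that("grid search is reproducible and isolated from test data", {
  t <- make_signal_table(n_per_age = 8L, noise_sd = 0.5, seed = 2L)
  spec <- model_spec("knn", grid = list(k = c(3L, 5L, 7L),
                                        aggregation = c("mean", "median")),
                     seed = 7L)
  a <- grid_search_train(spec, t)
  b <- grid_search_train(spec, t)
  expect_identical(a$model$params, b$model$params)
  expect_equal(a$cv$r2, b$cv$r2, tolerance = 1e-15)
  expect_equal(a$cv$oof_pred, b$cv$oof_pred, tolerance = 1e-15)

  # the trained model depends only on the training table: the stored
  # standardizer is exactly the training-table fit, and predictions on any
  # external table leave the fitted state untouched
  st <- fit_standardizer(t)
  expect_equal(a$model$standardizer$means, st$means, tolerance = 1e-12)
  expect_equal(a$model$standardizer$sds, st$sds, tolerance = 1e-12)
  corrupted <- make_table(n = 10L, seed = 500L)
  invisible(predict(a$model, corrupted))
  c <- grid_search_train(spec, t)
  expect_identical(a$model$params, c$model$params)
  expect_equal(a$cv$mse, c$cv$mse, tolerance = 1e-15)
})

test_that("pooled CV metrics agree with recomputation from the pooled vector", {
  t <- make_signal_table(n_per_age = 8L, noise_sd = 0.4, seed = 3L)
  gs <- grid_search_train(model_spec("knn", grid = list(k = 4L,
                                                        aggregation = "mean"),
                                     seed = 1L), t)
  expect_equal(gs$cv$mse, mse(gs$cv$oof_pred, gs$cv$y), tolerance = 1e-12)
  expect_equal(gs$cv$r2, r_squared(gs$cv$oof_pred, gs$cv$y), tolerance = 1e-12)
})

test_that("a memorizing 1-NN model has zero error on its own training set", {
  t <- make_table(n = 12L, seed = 21L)
  gs <- grid_search_train(model_spec("knn", grid = list(k = 1L,
                                                        aggregation = "mean"),
                                     cv_folds = 3L, seed = 1L), t)
  ev <- evaluate_model(gs$model, t)
  expect_equal(ev$mse, 0, tolerance = 1e-12)
})

test_that("knn aggregation honours mean versus median", {
  X <- matrix(c(0, 1, 2, 10), ncol = 1)
  fit <- structure(list(X = X, y = c(1, 2, 3, 100), k = 3L,
                        aggregation = "mean"), class = "ag_knn")
  expect_equal(unname(predict(fit, matrix(0.5))), 2)
  fit$aggregation <- "median"
  expect_equal(unname(predict(fit, matrix(0.5))), 2)
  fit$k <- 4L
  expect_equal(unname(predict(fit, matrix(0.5))), median(c(1, 2, 3, 100)))
  fit$aggregation <- "mean"
  expect_equal(unname(predict(fit, matrix(0.5))), 26.5)
})

test_that("nonlinear age-feature links favour the nonlinear regressors", {
  # every feature follows a common factor growing quadratically in age: a
  # linear model cannot follow the curvature, kernel and network models can;
  # majority vote over 10 seeds
  wins_svr <- 0L; wins_mlp <- 0L
  for (seed in 1:10) {
    withr::with_seed(seed * 100L, {
      age <- rep(c(2, 3, 4), each = 8L)
      load <- runif(9, 0.5, 1.5)
      feats <- sapply(seq_len(9), function(j) {
        10 + 2 * load[j] * (age - 2)^2 + rnorm(24, sd = 0.15)
      })
      colnames(feats) <- ag_feature_names()
      t <- as_sample_table(data.frame(sample_id = sprintf("s%02d", 1:24),
                                      region = "A", age = age, feats))
    })
    en <- grid_search_train(model_spec("elastic_net",
      grid = list(alpha = 1e-2, l1_ratio = 0.5), seed = seed), t)
    sv <- grid_search_train(model_spec("svr_rbf",
      grid = list(C = 10, gamma = list("scale")), seed = seed), t)
    ml <- grid_search_train(model_spec("mlp",
      grid = list(hidden = list(8L), alpha = 1e-3, learning_rate = 1e-2),
      seed = seed), t)
    if (sv$cv$mse <= en$cv$mse) wins_svr <- wins_svr + 1L
    if (ml$cv$mse <= en$cv$mse) wins_mlp <- wins_mlp + 1L
  }
  expect_gte(wins_svr, 6L)
  expect_gte(wins_mlp, 6L)
})

test_that("permutation importance ranks the dominant feature first", {
  t <- make_signal_table(n_per_age = 10L, signal = c(weight = 3),
                         noise_sd = 0.3, seed = 5L)
  gs <- grid_search_train(model_spec("knn", grid = list(k = 3L,
                                                        aggregation = "mean"),
                                     seed = 1L), t)
  imp <- permutation_importance(gs$model, t, repeats = 5L, seed = 9L)
  expect_equal(imp$feature[1L], "weight")
  expect_gt(imp$importance[1L], max(imp$importance[-1L]))
  # features carrying no signal sit near zero
  expect_lt(max(abs(imp$importance[imp$feature != "weight"])), 0.2)
  # deterministic under seed
  imp2 <- permutation_importance(gs$model, t, repeats = 5L, seed = 9L)
  expect_equal(imp, imp2)
})

test_that("the mlp regressor is deterministic and fits a smooth function", {
  withr::with_seed(31L, {
    X <- matrix(runif(60, -2, 2), ncol = 2)
    y <- sin(X[, 1]) + 0.5 * X[, 2]
  })
  f1 <- mlp_fit(X, y, hidden = c(16L), learning_rate = 1e-2, seed = 4L)
  f2 <- mlp_fit(X, y, hidden = c(16L), learning_rate = 1e-2, seed = 4L)
  expect_identical(predict(f1, X), predict(f2, X))
  expect_gt(r_squared(predict(f1, X), y), 0.95)
  expect_true(all(is.finite(predict(f1, matrix(c(50, -50), ncol = 2)))))
})
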