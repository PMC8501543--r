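#' Mean squared error
#'
#' `sum((pred - true)^2) / n`, in squared years for age predictions.
#'
#' @param pred,true Equal-length numeric vectors.
#' @return Non-negative scalar.
#' @export
mse <- function(pred, true) {
  if (length(pred) != length(true)) stop("length mismatch", call. = FALSE)
  if (length(pred) < 1L) stop("empty vectors", call. = FALSE)
  mean((pred - true)^2)
}

#' Coefficient of determination
#'
#' Standard form: `1 - sum((pred - true)^2) / sum((true - mean(true))^2)`.
#' `form = "printed"` instead divides by `sum((pred - mean(true))^2)`, a
#' non-standard variant kept available for comparison with sources that
#' print it that way.
#'
#' @param pred,true Equal-length numeric vectors (length >= 2); `true` must
#'   not be constant (`pred` must not be constant at `mean(true)` under the
#'   printed form).
#' @param form `"standard"` (default) or `"printed"`.
#' @return Scalar <= 1 (standard form).
#' @export
r_squared <- function(pred, true, form = c("standard", "printed")) {
  form <- match.arg(form)
  if (length(pred) != length(true)) stop("length mismatch", call. = FALSE)
  if (length(true) < 2L) stop("need at least 2 observations", call. = FALSE)
  denom <- if (form == "standard") sum((true - mean(true))^2)
           else sum((pred - mean(true))^2)
  if (denom == 0) stop("undefined denominator: constant reference values",
                       call. = FALSE)
  1 - sum((pred - true)^2) / denom
}

#' Hyperparameter grids and model specification
#'
#' Default grids span conventional log-spaced regimes for each algorithm;
#' every grid is overridable. Candidates are ordered smallest-complexity
#' first and ties in cross-validated score go to the earlier candidate, so
#' selection is deterministic.
#'
#' @param algorithm One of `"elastic_net"`, `"knn"`, `"svr_rbf"`, `"mlp"`.
#' @return Named list of candidate value vectors/lists.
#' @export
default_grid <- function(algorithm) {
  switch(algorithm,
    elastic_net = list(alpha = c(1e-3, 1e-2, 0.1, 1, 10),
                       l1_ratio = c(seq(0.1, 0.9, by = 0.1), 1.0)),
    knn = list(k = 1:15, aggregation = c("mean", "median")),
    svr_rbf = list(C = c(0.1, 1, 10, 100),
                   gamma = list(1e-3, 1e-2, 0.1, 1, "scale")),
    mlp = list(hidden = list(8L, 16L, 32L, c(8L, 8L)),
               alpha = c(1e-4, 1e-3, 1e-2),
               learning_rate = c(1e-3, 1e-2)),
    stop("unknown algorithm: ", algorithm, call. = FALSE))
}

#' @rdname default_grid
#' @param grid Hyperparameter grid (named list of candidate values); defaults
#'   to [default_grid()].
#' @param cv_folds Number of cross-validation folds (default 5).
#' @param seed Integer seed controlling fold assignment and stochastic fits.
#' @export
model_spec <- function(algorithm = c("elastic_net", "knn", "svr_rbf", "mlp"),
                       grid = default_grid(algorithm), cv_folds = 5L,
                       seed = 1L) {
  algorithm <- match.arg(algorithm)
  if (length(grid) == 0L || any(lengths(grid) == 0L)) {
    stop("hyperparameter grid must be non-empty", call. = FALSE)
  }
  if (cv_folds < 2L) stop("cv_folds must be >= 2", call. = FALSE)
  structure(list(algorithm = algorithm, grid = grid,
                 cv_folds = as.integer(cv_folds), seed = as.integer(seed)),
            class = "ag_model_spec")
}

grid_candidates <- function(grid) {
  idx <- do.call(expand.grid, c(lapply(rev(grid), seq_along),
                                KEEP.OUT.ATTRS = FALSE))
  idx <- idx[, rev(names(idx)), drop = FALSE]  # first parameter varies slowest
  lapply(seq_len(nrow(idx)), function(i) {
    stats::setNames(lapply(names(grid), function(p) grid[[p]][[idx[i, p]]]),
                    names(grid))
  })
}

resolve_gamma <- function(gamma, X) {
  if (identical(gamma, "scale")) {
    v <- stats::var(as.vector(X)) * (length(X) - 1L) / length(X)
    1 / (ncol(X) * v)
  } else as.numeric(gamma)
}

fit_algorithm <- function(algorithm, params, X, y, seed) {
  switch(algorithm,
    elastic_net = glmnet::glmnet(X, y, alpha = params$l1_ratio,
                                 lambda = params$alpha, standardize = FALSE),
    knn = structure(list(X = X, y = y, k = params$k,
                         aggregation = params$aggregation),
                    class = "ag_knn"),
    svr_rbf = e1071::svm(x = X, y = y, type = "eps-regression",
                         kernel = "radial", cost = params$C,
                         gamma = resolve_gamma(params$gamma, X),
                         scale = FALSE),
    mlp = mlp_fit(X, y, hidden = params$hidden, alpha = params$alpha,
                  learning_rate = params$learning_rate, seed = seed))
}

predict_algorithm <- function(algorithm, fit, X) {
  switch(algorithm,
    elastic_net = drop(stats::predict(fit, newx = X)),
    knn = predict.ag_knn(fit, X),
    svr_rbf = unname(stats::predict(fit, X)),
    mlp = stats::predict(fit, X))
}

#' @export
predict.ag_knn <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  agg <- if (identical(object$aggregation, "median")) stats::median else mean
  apply(newdata, 1L, function(q) {
    d <- sqrt(colSums((t(object$X) - q)^2))
    nn <- order(d)[seq_len(object$k)]       # stable: ties by index order
    agg(object$y[nn])
  })
}

stratified_folds <- function(y, k, seed) {
  fold <- integer(length(y))
  withr::with_seed(seed, {
    for (lev in unique(y)) {
      idx <- which(y == lev)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

#' Grid-search cross-validated training of an age regressor
#'
#' Fivefold (by default) shuffled cross-validation, stratified by age level.
#' Inside every fold the features are standardized with that fold's training
#' statistics only, so no information flows from held-out rows into the fit.
#' The candidate maximizing the mean out-of-fold coefficient of
#' determination is selected (folds whose held-out ages are constant are
#' skipped for R-squared with a warning; if no fold admits R-squared the
#' lowest mean MSE wins), the model is refit on the full training table, and
#' pooled out-of-fold predictions at the chosen candidate give the reported
#' CV metrics.
#'
#' @param spec An `ag_model_spec`.
#' @param train A `sample_table`.
#' @return List with `model` (an `ag_regressor`: final fit + training
#'   standardizer + chosen hyperparameters) and `cv` (an `ag_cv_result`:
#'   pooled out-of-fold predictions, `r2`, `mse`, per-candidate score table).
#' @export
grid_search_train <- function(spec, train) {
  stopifnot(inherits(spec, "ag_model_spec"))
  train <- as_sample_table(train)
  if (nrow(train) == 0L) stop("empty training table", call. = FALSE)
  X_raw <- feature_matrix(train)
  y <- train$age
  k <- spec$cv_folds
  if (k > nrow(train)) stop("cv_folds exceeds training size", call. = FALSE)
  fold <- stratified_folds(y, k, spec$seed)
  candidates <- grid_candidates(spec$grid)

  oof_all <- matrix(NA_real_, nrow(train), length(candidates))
  warned_const <- FALSE
  for (f in seq_len(k)) {
    hold <- fold == f
    st <- fit_standardizer(X_raw[!hold, , drop = FALSE], fitted_on = "cv-fold")
    Xtr <- apply_standardizer(st, X_raw[!hold, , drop = FALSE])
    Xho <- apply_standardizer(st, X_raw[hold, , drop = FALSE])
    for (ci in seq_along(candidates)) {
      fit <- fit_algorithm(spec$algorithm, candidates[[ci]], Xtr, y[!hold],
                           seed = spec$seed + f)
      oof_all[hold, ci] <- predict_algorithm(spec$algorithm, fit, Xho)
    }
  }

  fold_r2 <- matrix(NA_real_, k, length(candidates))
  fold_mse <- matrix(NA_real_, k, length(candidates))
  for (f in seq_len(k)) {
    hold <- fold == f
    const <- stats::var(y[hold]) == 0 || sum(hold) < 2L
    if (const && !warned_const) {
      warning("fold with constant held-out ages: R-squared skipped there")
      warned_const <- TRUE
    }
    for (ci in seq_along(candidates)) {
      fold_mse[f, ci] <- mse(oof_all[hold, ci], y[hold])
      if (!const) fold_r2[f, ci] <- r_squared(oof_all[hold, ci], y[hold])
    }
  }
  mean_r2 <- colMeans(fold_r2, na.rm = TRUE)
  mean_mse <- colMeans(fold_mse)
  best <- if (all(is.nan(mean_r2))) which.min(mean_mse) else which.max(mean_r2)
  chosen <- candidates[[best]]

  st_full <- fit_standardizer(X_raw, fitted_on = "training")
  fit_full <- fit_algorithm(spec$algorithm, chosen,
                            apply_standardizer(st_full, X_raw), y,
                            seed = spec$seed)
  model <- structure(list(spec = spec, params = chosen, fit = fit_full,
                          standardizer = st_full),
                     class = "ag_regressor")
  cv <- structure(list(oof_pred = oof_all[, best], fold = fold, y = y,
                       r2 = r_squared(oof_all[, best], y),
                       mse = mse(oof_all[, best], y),
                       candidate_scores = data.frame(
                         candidate = seq_along(candidates),
                         mean_r2 = mean_r2, mean_mse = mean_mse),
                       chosen = best),
                  class = "ag_cv_result")
  list(model = model, cv = cv)
}

#' Predict cultivation ages with a trained regressor
#'
#' @param object An `ag_regressor`.
#' @param newdata A `sample_table` or raw feature matrix (original units;
#'   the stored training standardizer is applied internally).
#' @param ... Unused.
#' @return Numeric vector of predicted ages (years).
#' @export
predict.ag_regressor <- function(object, newdata, ...) {
  X <- apply_standardizer(object$standardizer, newdata)
  predict_algorithm(object$spec$algorithm, object$fit, X)
}

#' Evaluate a trained regressor on a test table
#'
#' @param model An `ag_regressor`.
#' @param test A `sample_table`.
#' @return List with `mse`, `r2` (NA when the test ages are constant, as for
#'   single-age test regions) and the prediction vector.
#' @export
evaluate_model <- function(model, test) {
  test <- as_sample_table(test)
  pred <- stats::predict(model, test)
  r2 <- if (stats::var(test$age) == 0 || nrow(test) < 2L) NA_real_
        else r_squared(pred, test$age)
  list(mse = mse(pred, test$age), r2 = r2, pred = pred)
}

#' Permutation importance of the nine features
#'
#' Importance of a feature is the mean drop in the model's coefficient of
#' determination when that feature's column is randomly permuted, over
#' `repeats` independent permutations. Computed on the training table by
#' default. Deterministic under `seed`.
#'
#' @param model An `ag_regressor`.
#' @param t A `sample_table` with known ages.
#' @param repeats Number of permutations per feature.
#' @param seed Integer seed.
#' @return data.frame (feature, importance) sorted by decreasing importance.
#' @export
permutation_importance <- function(model, t, repeats = 10L, seed = 1L) {
  t <- as_sample_table(t)
  X <- feature_matrix(t)
  y <- t$age
  base <- r_squared(stats::predict(model, X), y)
  imp <- withr::with_seed(seed, {
    vapply(ag_feature_names(), function(f) {
      drops <- vapply(seq_len(repeats), function(r) {
        Xp <- X
        Xp[, f] <- Xp[sample.int(nrow(Xp)), f]
        base - r_squared(stats::predict(model, Xp), y)
      }, numeric(1L))
      mean(drops)
    }, numeric(1L))
  })
  out <- data.frame(feature = names(imp), importance = unname(imp),
                    stringsAsFactors = FALSE)
  out[order(-out$importance), , drop = FALSE]
}

#' Train the study's four regressors
#'
#' Convenience wrapper running [grid_search_train()] for elastic net, k-NN,
#' RBF support-vector regression and the MLP with their default (or
#' supplied) grids.
#'
#' @param train A `sample_table`.
#' @param seed Integer seed shared by all four searches.
#' @param grids Optional named list overriding [default_grid()] per
#'   algorithm.
#' @param cv_folds Folds for cross-validation.
#' @return Named list of `grid_search_train()` results, one per algorithm.
#' @export
train_all_models <- function(train, seed = 1L, grids = list(), cv_folds = 5L) {
  algs <- c("elastic_net", "knn", "svr_rbf", "mlp")
  stats::setNames(lapply(algs, function(a) {
    g <- if (!is.null(grids[[a]])) grids[[a]] else default_grid(a)
    grid_search_train(model_spec(a, grid = g, cv_folds = cv_folds, seed = seed),
                      train)
  }), algs)
}
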