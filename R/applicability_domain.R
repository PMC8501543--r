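# k-NN Euclidean-distance applicability domain. A model's domain is the set
# of queries whose mean distance to their k nearest training samples (TS)
# does not exceed TAD = mean(dbar) + Z * sd(dbar), where dbar_i is training
# sample i's mean distance to its own k nearest training neighbours (self
# excluded). Distances are taken in the training-standardized feature space
# by default, so grams, centimetres and percentages contribute comparably.

# sorted distances from each row of `a` to rows of `b`, excluding an exact
# self-match by index when `exclude_self`
sorted_cross_dist <- function(a, b, exclude_self = FALSE) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d <- sqrt(pmax(d2, 0))
  m <- ncol(d) - as.integer(exclude_self)
  res <- vapply(seq_len(nrow(a)), function(i) {
    di <- d[i, ]
    if (exclude_self) di <- di[-i]
    sort(di)
  }, numeric(m))
  if (m == 1L) matrix(res, ncol = 1L) else t(res)
}

#' Fit a k-NN distance applicability domain
#'
#' For each training sample, computes the mean Euclidean distance to its
#' `k` nearest neighbours within the training set (self excluded); the
#' domain threshold is `TAD = mean(dbar) + Z * sigma` with `sigma` the
#' sample standard deviation (n - 1) of those mean distances.
#'
#' @param x Training features: a `sample_table` (standardizer fitted on it
#'   and stored, distances taken in standardized space) or a numeric matrix
#'   used as-is (pass pre-standardized coordinates, or raw ones for an
#'   unstandardized-distance sensitivity analysis).
#' @param k Neighbour count, integer in `[1, n - 1]`.
#' @param Z Empirical threshold multiplier.
#' @return Object of class `ad_model`: `train` (matrix in distance space),
#'   `k`, `Z`, `dbar_train`, `sigma`, `tad`, `standardizer` (NULL for
#'   matrix input).
#' @export
fit_ad <- function(x, k, Z) {
  st <- NULL
  if (inherits(x, "sample_table")) {
    st <- fit_standardizer(x, fitted_on = "ad-training")
    m <- apply_standardizer(st, x)
  } else {
    m <- as.matrix(x)
  }
  n <- nrow(m)
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  if (k >= n) stop("k must be <= n - 1 (self excluded)", call. = FALSE)
  sorted <- sorted_cross_dist(m, m, exclude_self = TRUE)
  dbar <- rowMeans(sorted[, seq_len(k), drop = FALSE])
  sigma <- stats::sd(dbar)
  structure(list(train = m, k = as.integer(k), Z = Z,
                 dbar_train = dbar, sigma = sigma,
                 tad = mean(dbar) + Z * sigma,
                 standardizer = st),
            class = "ad_model")
}

ad_query_matrix <- function(ad, query) {
  if (inherits(query, "sample_table")) {
    if (is.null(ad$standardizer)) {
      stop("ad_model was fitted on a matrix; supply standardized coordinates",
           call. = FALSE)
    }
    apply_standardizer(ad$standardizer, query)
  } else {
    q <- query
    if (is.null(dim(q))) q <- matrix(q, nrow = 1L)
    if (!is.null(ad$standardizer)) q <- apply_standardizer(ad$standardizer, q)
    q
  }
}

#' Score queries against an applicability domain
#'
#' Each query's score `TS` is its mean Euclidean distance to its `k`
#' nearest training samples; the query is inside the domain when
#' `TS <= TAD` (a score exactly at the threshold counts as inside).
#'
#' @param ad An `ad_model`.
#' @param query A `sample_table`, a feature matrix, or a single feature
#'   vector. Tables and raw matrices are standardized with the stored
#'   training standardizer when the domain was fitted on a table.
#' @return data.frame with columns `ts`, `tad`, `inside` (one row per query).
#' @export
score_query <- function(ad, query) {
  stopifnot(inherits(ad, "ad_model"))
  q <- ad_query_matrix(ad, query)
  sorted <- sorted_cross_dist(q, ad$train, exclude_self = FALSE)
  ts <- rowMeans(sorted[, seq_len(ad$k), drop = FALSE])
  data.frame(ts = ts, tad = ad$tad, inside = ts <= ad$tad)
}

#' Scan the (k, Z) grid of applicability-domain settings
#'
#' For every combination of neighbour count `k` and multiplier `Z`, fits the
#' domain on the training table, classifies all test rows, and records the
#' threshold, the number of in-domain (ID) test samples, and each model's
#' MSE restricted to its ID rows (`NA` when a grid point admits no test
#' sample). The default ranges are k = 1..12 and Z from 0.5 towards 3.0 in
#' steps of 0.2 (13 values), a 156-point grid.
#'
#' @param train A `sample_table` (training set).
#' @param tests Named list of `sample_table`s (test sets).
#' @param models Named list of `ag_regressor`s (may be empty).
#' @param k_range Integer vector of neighbour counts.
#' @param z_range Numeric vector of Z multipliers.
#' @return Long-format data.frame: `k, Z, tad, test, id_count, model,
#'   mse_inside` (class `ad_scan`), one row per (k, Z, test, model); with no
#'   models a single `model = NA` row per (k, Z, test).
#' @export
ad_scan <- function(train, tests, models = list(),
                    k_range = 1:12, z_range = seq(0.5, 3.0, by = 0.2)) {
  if (length(k_range) == 0L || length(z_range) == 0L) {
    stop("empty scan range", call. = FALSE)
  }
  train <- as_sample_table(train)
  if (is.null(names(tests)) || any(names(tests) == "")) {
    names(tests) <- paste0("test", seq_along(tests))
  }
  st <- fit_standardizer(train, fitted_on = "ad-training")
  m <- apply_standardizer(st, train)
  sorted_train <- sorted_cross_dist(m, m, exclude_self = TRUE)
  sorted_tests <- lapply(tests, function(tt) {
    sorted_cross_dist(apply_standardizer(st, tt), m)
  })
  preds <- lapply(tests, function(tt) {
    lapply(models, function(gs) {
      mod <- if (inherits(gs, "ag_regressor")) gs else gs$model
      stats::predict(mod, tt)
    })
  })
  model_names <- if (length(models) > 0L) names(models) else NA_character_

  rows <- list()
  for (k in k_range) {
    dbar <- rowMeans(sorted_train[, seq_len(k), drop = FALSE])
    mu <- mean(dbar); sigma <- stats::sd(dbar)
    ts_k <- lapply(sorted_tests, function(s) {
      rowMeans(s[, seq_len(k), drop = FALSE])
    })
    for (Z in z_range) {
      tad <- mu + Z * sigma
      for (tn in names(tests)) {
        inside <- ts_k[[tn]] <= tad
        for (mn in model_names) {
          mse_in <- NA_real_
          if (!is.na(mn) && any(inside)) {
            mse_in <- mse(preds[[tn]][[mn]][inside], tests[[tn]]$age[inside])
          }
          rows[[length(rows) + 1L]] <- data.frame(
            k = k, Z = Z, tad = tad, test = tn, id_count = sum(inside),
            model = mn, mse_inside = mse_in, stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("ad_scan", "data.frame")
  out
}

#' Inside/outside-domain error decomposition
#'
#' At a fixed domain (one `k`, `Z`), reports per model and per test table
#' the ID and OD sample counts and the MSE within each group, plus a pooled
#' row across all test tables.
#'
#' @param ad An `ad_model` fitted on the training `sample_table`.
#' @param tests Named list of `sample_table`s.
#' @param models Named list of `ag_regressor`s (or `grid_search_train()`
#'   results).
#' @return data.frame: `model, test, n_id, n_od, mse_id, mse_od` with
#'   `test = "pooled"` rows appended. Empty groups yield `NA` MSE.
#' @export
id_od_report <- function(ad, tests, models) {
  stopifnot(inherits(ad, "ad_model"))
  if (is.null(names(tests)) || any(names(tests) == "")) {
    names(tests) <- paste0("test", seq_along(tests))
  }
  decisions <- lapply(tests, function(tt) score_query(ad, tt)$inside)
  rows <- list()
  for (mn in names(models)) {
    gs <- models[[mn]]
    mod <- if (inherits(gs, "ag_regressor")) gs else gs$model
    pool_pred <- numeric(0); pool_true <- numeric(0); pool_in <- logical(0)
    for (tn in names(tests)) {
      pred <- stats::predict(mod, tests[[tn]])
      inside <- decisions[[tn]]
      true <- tests[[tn]]$age
      rows[[length(rows) + 1L]] <- data.frame(
        model = mn, test = tn, n_id = sum(inside), n_od = sum(!inside),
        mse_id = if (any(inside)) mse(pred[inside], true[inside]) else NA_real_,
        mse_od = if (any(!inside)) mse(pred[!inside], true[!inside]) else NA_real_,
        stringsAsFactors = FALSE)
      pool_pred <- c(pool_pred, pred); pool_true <- c(pool_true, true)
      pool_in <- c(pool_in, inside)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      model = mn, test = "pooled", n_id = sum(pool_in), n_od = sum(!pool_in),
      mse_id = if (any(pool_in)) mse(pool_pred[pool_in], pool_true[pool_in]) else NA_real_,
      mse_od = if (any(!pool_in)) mse(pool_pred[!pool_in], pool_true[!pool_in]) else NA_real_,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
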