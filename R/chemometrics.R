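#' Principal component analysis of standardized feature profiles
#'
#' Standardizes the nine features (sample SD convention) and decomposes the
#' matrix by singular values. By default the standardizer is fitted on the
#' table being decomposed (the pooled train-plus-test table for a
#' distribution diagnostic); pass a pre-fitted standardizer to project new
#' tables into an existing component space. Loading signs are fixed so each
#' component's largest-magnitude loading is positive, making outputs
#' deterministic and comparable.
#'
#' @param t A `sample_table` (>= 2 rows).
#' @param standardizer Optional `ag_standardizer`; fitted on `t` when NULL.
#' @return Object of class `ag_pca`: `loadings` (9 x 9 orthonormal),
#'   `explained_variance_ratio` (non-increasing, sums to 1), `sdev`,
#'   `standardizer`.
#' @export
fit_pca <- function(t, standardizer = NULL) {
  m <- if (is.matrix(t)) t else feature_matrix(t)
  if (nrow(m) < 2L) stop("PCA needs at least 2 samples", call. = FALSE)
  if (is.null(standardizer)) standardizer <- fit_standardizer(m, fitted_on = "pca")
  z <- apply_standardizer(standardizer, m)
  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  load <- pc$rotation
  flip <- apply(load, 2L, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  load <- sweep(load, 2L, flip, "*")
  ev <- pc$sdev^2
  structure(list(loadings = load,
                 explained_variance_ratio = ev / sum(ev),
                 sdev = pc$sdev,
                 standardizer = standardizer),
            class = "ag_pca")
}

#' Project a table onto fitted principal components
#'
#' @param model An `ag_pca`.
#' @param t A `sample_table` or feature matrix.
#' @param n_components Number of leading components to keep (default all).
#' @return Score matrix (rows = samples).
#' @export
project_pca <- function(model, t, n_components = ncol(model$loadings)) {
  stopifnot(inherits(model, "ag_pca"))
  z <- apply_standardizer(model$standardizer, t)
  z %*% model$loadings[, seq_len(n_components), drop = FALSE]
}

# classical pooled-variance two-sample t-test, with explicit conventions for
# degenerate (zero pooled variance) groups that t.test() refuses: equal means
# give t = 0, p = 1; unequal means give t = +/-Inf, p = 0
pooled_t_test <- function(x, y) {
  nx <- length(x); ny <- length(y)
  df <- nx + ny - 2L
  sp2 <- ((nx - 1L) * stats::var(x) + (ny - 1L) * stats::var(y)) / df
  delta <- mean(x) - mean(y)
  if (sp2 == 0) {
    if (delta == 0) return(list(t = 0, df = df, p = 1))
    return(list(t = sign(delta) * Inf, df = df, p = 0))
  }
  tval <- delta / sqrt(sp2 * (1 / nx + 1 / ny))
  list(t = tval, df = df, p = 2 * stats::pt(-abs(tval), df))
}

significance_tier <- function(p) {
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 0.05, Inf),
      labels = c("****", "***", "**", "*", "ns"), right = FALSE)
}

#' Per-age feature trends with pairwise Student's t-tests
#'
#' For each feature: group mean, SD and n per age, plus classical
#' pooled-variance two-sample two-tailed t-tests for every pair of ages,
#' with significance tiers at p < 0.05 / 0.01 / 0.001 / 0.0001. Groups with
#' fewer than 2 samples are summarized but excluded from tests with a
#' warning.
#'
#' @param t A `sample_table`.
#' @return List of class `trend_report`: `groups` (feature, age, mean, sd, n)
#'   and `tests` (feature, age_a, age_b, t, df, p, tier).
#' @export
trend_report <- function(t) {
  t <- as_sample_table(t)
  ages <- sort(unique(t$age))
  feats <- ag_feature_names()

  groups <- do.call(rbind, lapply(feats, function(f) {
    do.call(rbind, lapply(ages, function(a) {
      v <- t[[f]][t$age == a]
      data.frame(feature = f, age = a, mean = mean(v),
                 sd = if (length(v) >= 2L) stats::sd(v) else NA_real_,
                 n = length(v), stringsAsFactors = FALSE)
    }))
  }))

  testable <- ages[vapply(ages, function(a) sum(t$age == a) >= 2L, logical(1L))]
  if (length(testable) < length(ages)) {
    warning("age group(s) with n < 2 excluded from t-tests: ",
            paste(setdiff(ages, testable), collapse = ", "))
  }
  tests <- NULL
  if (length(testable) >= 2L) {
    pairs <- utils::combn(testable, 2L)
    tests <- do.call(rbind, lapply(feats, function(f) {
      do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
        a <- pairs[1L, j]; b <- pairs[2L, j]
        ht <- pooled_t_test(t[[f]][t$age == a], t[[f]][t$age == b])
        data.frame(feature = f, age_a = a, age_b = b,
                   t = ht$t, df = ht$df, p = ht$p, stringsAsFactors = FALSE)
      }))
    }))
    tests$tier <- as.character(significance_tier(tests$p))
  }
  structure(list(groups = groups, tests = tests), class = "trend_report")
}
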