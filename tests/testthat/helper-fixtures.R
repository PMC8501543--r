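# Shared fixture builders. Everything is generated in code at test time.

# minimal valid table from a compact spec: one row per (region, age) repeated
make_table <- function(n = 6L, regions = "A", ages = c(2, 3, 4), seed = 42L) {
  withr::with_seed(seed, {
    region <- rep(regions, length.out = n)
    age <- rep(ages, length.out = n)
    feats <- matrix(abs(stats::rnorm(n * 9, mean = 10, sd = 2)),
                    nrow = n, dimnames = list(NULL, ag_feature_names()))
    as_sample_table(data.frame(sample_id = sprintf("s%02d", seq_len(n)),
                               region = region, age = age, feats,
                               stringsAsFactors = FALSE))
  })
}

# table whose only age signal is a linear trend in chosen features
make_signal_table <- function(n_per_age = 10L, ages = c(2, 3, 4),
                              signal = c(weight = 3), noise_sd = 0.2,
                              seed = 1L) {
  withr::with_seed(seed, {
    age <- rep(ages, each = n_per_age)
    n <- length(age)
    feats <- matrix(stats::rnorm(n * 9, mean = 10, sd = noise_sd),
                    nrow = n, dimnames = list(NULL, ag_feature_names()))
    for (f in names(signal)) {
      feats[, f] <- feats[, f] + signal[[f]] * (age - min(ages))
    }
    as_sample_table(data.frame(sample_id = sprintf("s%03d", seq_len(n)),
                               region = "A", age = age, feats,
                               stringsAsFactors = FALSE))
  })
}

# single-point grids: fast, deterministic candidates for tests whose subject
# is not hyperparameter tuning
tiny_grids <- function() {
  list(elastic_net = list(alpha = 1e-2, l1_ratio = 0.5),
       knn = list(k = 5L, aggregation = "mean"),
       svr_rbf = list(C = 10, gamma = list("scale")),
       mlp = list(hidden = list(8L), alpha = 1e-2, learning_rate = 1e-3))
}

# independent brute-force oracle for the k-NN distance applicability domain:
# explicit double loops over the full pairwise distance matrix
brute_force_ad <- function(train, k, Z, query = NULL) {
  n <- nrow(train)
  dmat <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      dmat[i, j] <- sqrt(sum((train[i, ] - train[j, ])^2))
    }
  }
  dbar <- numeric(n)
  for (i in seq_len(n)) {
    dbar[i] <- mean(sort(dmat[i, -i])[seq_len(k)])
  }
  sigma <- stats::sd(dbar)
  tad <- mean(dbar) + Z * sigma
  ts <- NULL
  if (!is.null(query)) {
    ts <- apply(query, 1L, function(q) {
      dq <- apply(train, 1L, function(x) sqrt(sum((x - q)^2)))
      mean(sort(dq)[seq_len(k)])
    })
  }
  list(dbar = dbar, sigma = sigma, tad = tad, ts = ts)
}
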