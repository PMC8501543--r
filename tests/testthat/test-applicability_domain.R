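test_that("three collinear points reproduce the hand-worked threshold", {
  m <- matrix(c(0, 1, 2), ncol = 1)

  # k = 1: every point's nearest neighbour is at distance 1, sigma = 0
  ad1 <- fit_ad(m, k = 1L, Z = 5)
  expect_equal(ad1$dbar_train, c(1, 1, 1), tolerance = 1e-12)
  expect_equal(ad1$sigma, 0)
  expect_equal(ad1$tad, 1, tolerance = 1e-12)

  # k = 2: dbar = (1.5, 1, 1.5); sample SD = sqrt(1/12); tad = 4/3 + Z*sigma
  ad2 <- fit_ad(m, k = 2L, Z = 1)
  expect_equal(ad2$dbar_train, c(1.5, 1, 1.5), tolerance = 1e-12)
  expect_equal(ad2$sigma, sqrt(1 / 12), tolerance = 1e-12)
  expect_equal(ad2$tad, 4 / 3 + sqrt(1 / 12), tolerance = 1e-12)
  # (population-SD convention would give sqrt(1/18); assert it is not used)
  expect_gt(abs(ad2$sigma - sqrt(1 / 18)), 1e-6)

  expect_error(fit_ad(m, k = 0L, Z = 1), "k")
  expect_error(fit_ad(m, k = 3L, Z = 1), "k")
})

test_that("fit and scoring match a brute-force pairwise-distance oracle", {
  withr::with_seed(99L, {
    for (case in 1:100) {
      n <- sample(5:30, 1L)
      d <- sample(1:9, 1L)
      k <- sample(seq_len(n - 1L), 1L)
      Z <- runif(1, 0.2, 3)
      train <- matrix(rnorm(n * d), n, d)
      query <- matrix(rnorm(4 * d), 4, d)
      oracle <- brute_force_ad(train, k, Z, query)
      ad <- fit_ad(train, k, Z)
      expect_equal(ad$dbar_train, oracle$dbar, tolerance = 1e-10)
      expect_equal(ad$sigma, oracle$sigma, tolerance = 1e-10)
      expect_equal(ad$tad, oracle$tad, tolerance = 1e-10)
      sc <- score_query(ad, query)
      expect_equal(sc$ts, oracle$ts, tolerance = 1e-10)
      expect_identical(sc$inside, oracle$ts <= oracle$tad)
    }
  })
})

test_that("queries on and beyond the boundary behave as defined", {
  withr::with_seed(12L, train <- matrix(rnorm(40), 20, 2))
  ad <- fit_ad(train, k = 3L, Z = 1)

  # a training row itself at k >= 1 has small ts and sits inside
  sc <- score_query(ad, train[1L, ])
  expect_true(sc$inside)

  # ts exactly equal to tad counts as inside
  ad_edge <- ad; ad_edge$tad <- sc$ts
  sc_edge <- score_query(ad_edge, train[1L, ])
  expect_true(sc_edge$inside)

  # arbitrarily remote query is outside
  far <- score_query(ad, c(1e6, -1e6))
  expect_false(far$inside)

  # query equal to a training row at k = 1 has ts = 0
  ad1 <- fit_ad(train, k = 1L, Z = 1)
  expect_equal(score_query(ad1, train[5L, ])$ts, 0, tolerance = 1e-12)
})

test_that("tad is strictly monotone in Z and ID sets are nested", {
  withr::with_seed(7L, {
    train <- matrix(rnorm(60), 20, 3)
    query <- matrix(rnorm(45), 15, 3)
  })
  zs <- seq(0.2, 3, by = 0.4)
  tads <- vapply(zs, function(z) fit_ad(train, 4L, z)$tad, numeric(1L))
  expect_true(all(diff(tads) > 0))
  prev <- rep(FALSE, nrow(query))
  for (z in zs) {
    inside <- score_query(fit_ad(train, 4L, z), query)$inside
    expect_true(all(!(prev & !inside)))  # once inside, stays inside as Z grows
    prev <- inside
  }
})

test_that("decisions are invariant to training row order and scale-coupled", {
  withr::with_seed(17L, {
    train <- matrix(rnorm(80), 20, 4)
    query <- matrix(rnorm(20), 5, 4)
    perm <- sample(20L)
  })
  ad <- fit_ad(train, 5L, 1.2)
  ad_p <- fit_ad(train[perm, ], 5L, 1.2)
  expect_equal(ad$tad, ad_p$tad, tolerance = 1e-12)
  expect_identical(score_query(ad, query)$inside,
                   score_query(ad_p, query)$inside)

  cc <- 3.7
  ad_s <- fit_ad(train * cc, 5L, 1.2)
  expect_equal(ad_s$tad, cc * ad$tad, tolerance = 1e-9)
  expect_equal(score_query(ad_s, query * cc)$ts, cc * score_query(ad, query)$ts,
               tolerance = 1e-9)
  expect_identical(score_query(ad_s, query * cc)$inside,
                   score_query(ad, query)$inside)
})

test_that("table-fitted domains standardize with training statistics", {
  spec <- default_cohort_spec(seed = 8L)
  sp <- split_cohort(spec)
  ad <- fit_ad(sp$train, k = 6L, Z = 1.6)
  st <- fit_standardizer(sp$train)
  manual <- fit_ad(apply_standardizer(st, sp$train), k = 6L, Z = 1.6)
  expect_equal(ad$tad, manual$tad, tolerance = 1e-12)
  expect_equal(score_query(ad, sp$tests[[1L]])$ts,
               score_query(manual, apply_standardizer(st, sp$tests[[1L]]))$ts,
               tolerance = 1e-12)
})

test_that("the k-by-Z scan has the configured shape and superset structure", {
  spec <- default_cohort_spec(seed = 2L)
  sp <- split_cohort(spec)
  names(sp$tests) <- c("near", "shifted")
  scan <- ad_scan(sp$train, sp$tests, models = list(),
                  k_range = 1:12, z_range = seq(0.5, 3.0, by = 0.2))
  expect_equal(nrow(unique(scan[, c("k", "Z")])), 12L * 13L)
  # id_count non-decreasing in Z at fixed k
  for (kk in c(1L, 6L, 12L)) {
    sub <- scan[scan$k == kk & scan$test == "near", ]
    sub <- sub[order(sub$Z), ]
    expect_true(all(diff(sub$id_count) >= 0L))
  }
  # huge Z admits everything
  all_in <- ad_scan(sp$train, sp$tests, models = list(),
                    k_range = c(3L, 6L), z_range = 1e6)
  expect_true(all(all_in$id_count[all_in$test == "near"] == 25L))
  expect_true(all(all_in$id_count[all_in$test == "shifted"] == 17L))
  expect_error(ad_scan(sp$train, sp$tests, k_range = integer(0)), "empty")
})

test_that("the ID/OD report decomposes errors and degenerates correctly", {
  spec <- default_cohort_spec(seed = 6L)
  sp <- split_cohort(spec)
  names(sp$tests) <- c("near", "shifted")
  fits <- train_all_models(sp$train, seed = 6L, grids = tiny_grids())

  # all-ID degenerate case: mse_id equals the plain test MSE
  ad_huge <- fit_ad(sp$train, k = 6L, Z = 1e6)
  rep <- id_od_report(ad_huge, sp$tests, fits)
  near_knn <- rep[rep$model == "knn" & rep$test == "near", ]
  expect_equal(near_knn$n_od, 0L)
  expect_equal(near_knn$mse_id,
               evaluate_model(fits$knn$model, sp$tests$near)$mse,
               tolerance = 1e-12)
  expect_true(is.na(near_knn$mse_od))

  # operating domain: ID and OD counts partition each test set
  ad <- fit_ad(sp$train, k = 6L, Z = 1.6)
  rep2 <- id_od_report(ad, sp$tests, fits)
  for (tn in c("near", "shifted")) {
    sub <- rep2[rep2$test == tn, ]
    expect_true(all(sub$n_id + sub$n_od ==
                      nrow(sp$tests[[tn]])))
  }
  pooled <- rep2[rep2$test == "pooled", ]
  expect_true(all(pooled$n_id + pooled$n_od == 42L))
})
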