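#' Specify a synthetic ginseng cohort
#'
#' Describes the generative model for synthetic sample tables: per-region
#' sample counts by age, a baseline feature mean at the youngest age,
#' additive per-year age slopes, region-level mean offsets, a displacement
#' vector applied to distribution-shifted regions, and independent Gaussian
#' noise per feature. Feature of a sample in region r at age a is
#' `baseline + age_slopes * (a - min_age) + region_offsets[[r]]
#' (+ shift_vector if the region's role is "shifted_test") + noise`.
#'
#' @param regions Named list; each element is `list(role =
#'   "train"|"near_test"|"shifted_test", n_per_age = c("2" = n2, ...))`.
#' @param age_levels Integer ages present in the design.
#' @param baseline,age_slopes,noise_sds Numeric 9-vectors in canonical
#'   feature order ([ag_feature_names()]); `noise_sds` strictly positive.
#' @param region_offsets Named list of 9-vectors (missing regions get zero).
#' @param shift_vector 9-vector added to every `shifted_test` region.
#' @param seed Integer seed; generation is a pure function of spec + seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(regions, age_levels, baseline, age_slopes,
                        region_offsets = list(), shift_vector = numeric(9),
                        noise_sds, seed = 1L) {
  nf <- length(ag_feature_names())
  stopifnot(length(baseline) == nf, length(age_slopes) == nf,
            length(shift_vector) == nf, length(noise_sds) == nf)
  if (length(regions) == 0L) stop("cohort spec needs at least one region", call. = FALSE)
  if (any(noise_sds <= 0)) stop("noise_sds must be strictly positive", call. = FALSE)
  for (r in names(regions)) {
    role <- regions[[r]]$role
    if (!role %in% c("train", "near_test", "shifted_test")) {
      stop("unknown region role: ", role, call. = FALSE)
    }
    if (any(regions[[r]]$n_per_age < 0)) stop("counts must be >= 0", call. = FALSE)
  }
  structure(list(regions = regions, age_levels = sort(age_levels),
                 baseline = stats::setNames(baseline, ag_feature_names()),
                 age_slopes = stats::setNames(age_slopes, ag_feature_names()),
                 region_offsets = region_offsets,
                 shift_vector = stats::setNames(shift_vector, ag_feature_names()),
                 noise_sds = stats::setNames(noise_sds, ag_feature_names()),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Default synthetic cohort mimicking the study design
#'
#' Three training regions spanning ages 2-4 (64 roots in total), one
#' near-distribution test region of 25 four-year-old roots, and one shifted
#' test region of 17 four-year-old roots displaced mainly in the extractive
#' percentages and the morphological features (lighter and shorter roots with
#' richer extractives). Weight, Rb1, Rd, Re and ethanol extractives carry
#' positive age slopes; the remaining features drift only slightly.
#'
#' @param seed Integer seed stored in the spec.
#' @return A `cohort_spec`.
#' @export
default_cohort_spec <- function(seed = 1L) {
  #              rg1   re   rb1   rd   f11  etoh  aq  len  wt
  baseline <- c(7.0, 12.0, 25.0, 4.0, 8.0, 28.0, 42.0, 7.0, 6.0)
  slopes   <- c(0.3,  2.5,  6.0, 1.5, 0.2,  3.0,  0.5, 1.0, 3.5)
  noise    <- c(0.8,  1.2,  2.5, 0.7, 0.9,  1.5,  1.8, 0.8, 1.2)
  shift    <- c(1.0, -2.0, -5.0, -1.5, 0.0,  3.0,  7.0, -3.0, -6.0)
  cohort_spec(
    regions = list(
      TrainA      = list(role = "train",        n_per_age = c("2" = 8, "3" = 8, "4" = 8)),
      TrainB      = list(role = "train",        n_per_age = c("2" = 7, "3" = 7, "4" = 7)),
      TrainC      = list(role = "train",        n_per_age = c("2" = 7, "3" = 6, "4" = 6)),
      NearTest    = list(role = "near_test",    n_per_age = c("4" = 25)),
      ShiftedTest = list(role = "shifted_test", n_per_age = c("4" = 17))
    ),
    age_levels = c(2L, 3L, 4L),
    baseline = baseline, age_slopes = slopes, noise_sds = noise,
    region_offsets = list(
      TrainA   = c(0, 0, 0, 0, 0, 0, 0, 1.0, 1.5),
      TrainC   = c(0, 0, 0, 0, 0, 1.0, 0, 0, -1.0),
      NearTest = c(0.8, 0, -2.0, 0, 0, 0, 0, 0, -0.5)
    ),
    shift_vector = shift, seed = seed
  )
}

#' Region labels of a cohort spec by role
#' @param spec A `cohort_spec`.
#' @param role One of `"train"`, `"near_test"`, `"shifted_test"`.
#' @return Character vector of region labels.
#' @export
regions_by_role <- function(spec, role) {
  names(Filter(function(r) identical(r$role, role), spec$regions))
}

#' Closed-form group mean of the generator
#'
#' Expected feature vector for a (region, age) cell, i.e. the generated mean
#' with the Gaussian noise set to zero.
#'
#' @param spec A `cohort_spec`.
#' @param region Region label.
#' @param age Age in years.
#' @return Named numeric 9-vector.
#' @export
cohort_cell_mean <- function(spec, region, age) {
  off <- spec$region_offsets[[region]]
  if (is.null(off)) off <- numeric(length(spec$baseline))
  mu <- spec$baseline + spec$age_slopes * (age - min(spec$age_levels)) + off
  if (identical(spec$regions[[region]]$role, "shifted_test")) {
    mu <- mu + spec$shift_vector
  }
  stats::setNames(mu, ag_feature_names())
}

#' Generate a synthetic sample table
#'
#' Draws the cohort described by `spec`: independent Gaussian noise per
#' feature around the closed-form cell means, truncated below so that
#' saponin contents and extractives stay non-negative and length/weight stay
#' strictly positive (truncation is negligible at the default
#' signal-to-noise ratio). Identical spec and seed give identical tables.
#'
#' @param spec A `cohort_spec`.
#' @return A `sample_table`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  nf <- length(ag_feature_names())
  rows <- withr::with_seed(spec$seed, {
    out <- list()
    for (region in names(spec$regions)) {
      npa <- spec$regions[[region]]$n_per_age
      for (age_chr in names(npa)) {
        age <- as.numeric(age_chr)
        n <- npa[[age_chr]]
        if (n == 0L) next
        mu <- cohort_cell_mean(spec, region, age)
        feats <- matrix(stats::rnorm(n * nf, mean = rep(mu, each = n),
                                     sd = rep(spec$noise_sds, each = n)),
                        nrow = n, ncol = nf,
                        dimnames = list(NULL, ag_feature_names()))
        nonneg <- c("rg1", "re", "rb1", "rd", "f11",
                    "ethanol_extract", "aqueous_extract")
        feats[, nonneg] <- pmax(feats[, nonneg], 0)
        feats[, c("length", "weight")] <- pmax(feats[, c("length", "weight")], 1e-3)
        out[[length(out) + 1L]] <- data.frame(
          sample_id = sprintf("%s_a%s_%02d", region, age_chr, seq_len(n)),
          region = region, age = age, feats,
          stringsAsFactors = FALSE)
      }
    }
    out
  })
  if (length(rows) == 0L) {
    empty <- data.frame(sample_id = character(), region = character(),
                        age = numeric(), stringsAsFactors = FALSE)
    for (f in ag_feature_names()) empty[[f]] <- numeric()
    class(empty) <- c("sample_table", "data.frame")
    return(empty)
  }
  as_sample_table(do.call(rbind, rows))
}

#' Split a generated cohort according to its spec roles
#'
#' Convenience wrapper: training regions become the training table, the
#' near-distribution and shifted regions become test tables 1 and 2.
#'
#' @param spec A `cohort_spec`.
#' @param t Optional pre-generated table (defaults to `generate_cohort(spec)`).
#' @return As [split_by_region()]: `list(train = ..., tests = list(near, shifted))`.
#' @export
split_cohort <- function(spec, t = generate_cohort(spec)) {
  split_by_region(t,
                  train_regions = regions_by_role(spec, "train"),
                  test_groups = list(regions_by_role(spec, "near_test"),
                                     regions_by_role(spec, "shifted_test")))
}
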