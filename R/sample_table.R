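#' Canonical feature order for ginseng sample tables
#'
#' The nine physicochemical features used throughout the pipeline, in their
#' fixed column order: contents of five saponins (Rg1, Re, Rb1, Rd,
#' pseudo-F11), ethanol and aqueous extractive percentages, root length (cm)
#' and root weight (g).
#'
#' @return Character vector of length 9.
#' @export
ag_feature_names <- function() {
  c("rg1", "re", "rb1", "rd", "f11",
    "ethanol_extract", "aqueous_extract", "length", "weight")
}

required_columns <- function() {
  c("sample_id", "region", "age", ag_feature_names())
}

#' Construct and validate a sample table
#'
#' A sample table is a `data.frame` with one row per ginseng root and columns
#' `sample_id`, `region`, `age` plus the nine features of
#' [ag_feature_names()]. Validation enforces unique sample ids, positive
#' integer-valued ages, non-negative saponin contents and extractives, and
#' strictly positive length and weight.
#'
#' @param df A data.frame carrying at least the required columns (any order;
#'   extra columns are dropped).
#' @return A validated `sample_table` (a `data.frame` subclass).
#' @export
as_sample_table <- function(df) {
  stopifnot(is.data.frame(df))
  have <- tolower(trimws(names(df)))
  names(df) <- have
  missing <- setdiff(required_columns(), have)
  if (length(missing) > 0L) {
    stop("sample table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df <- df[, required_columns(), drop = FALSE]
  df$sample_id <- as.character(df$sample_id)
  df$region <- trimws(as.character(df$region))

  for (col in c("age", ag_feature_names())) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(as.character(v)))
      bad <- which(is.na(vn) & !is.na(v))
      if (length(bad) > 0L) {
        stop(sprintf("non-numeric value in column '%s' at row %d", col, bad[1L]),
             call. = FALSE)
      }
      v <- vn
    }
    if (anyNA(v)) {
      stop(sprintf("missing value in column '%s' at row %d", col, which(is.na(v))[1L]),
           call. = FALSE)
    }
    df[[col]] <- v
  }

  dup <- duplicated(df$sample_id)
  if (any(dup)) {
    stop("duplicate sample_id: ", paste(unique(df$sample_id[dup]), collapse = ", "),
         call. = FALSE)
  }
  if (any(df$age <= 0)) stop("ages must be positive", call. = FALSE)
  nonneg <- c("rg1", "re", "rb1", "rd", "f11", "ethanol_extract", "aqueous_extract")
  for (col in nonneg) {
    if (any(df[[col]] < 0)) stop("negative value in column '", col, "'", call. = FALSE)
  }
  if (any(df$length <= 0)) stop("length must be > 0", call. = FALSE)
  if (any(df$weight <= 0)) stop("weight must be > 0", call. = FALSE)

  rownames(df) <- NULL
  class(df) <- c("sample_table", "data.frame")
  df
}

#' Read a sample table from CSV
#'
#' Comma-separated, UTF-8, `.` decimal, header required. Column names are
#' matched case-insensitively after trimming; row order is preserved.
#'
#' @param path Path to a CSV file with columns `sample_id, region, age, rg1,
#'   re, rb1, rd, f11, ethanol_extract, aqueous_extract, length, weight`.
#' @return A validated [as_sample_table()] object.
#' @export
read_sample_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        fileEncoding = "UTF-8")
  as_sample_table(df)
}

#' Write a sample table to CSV
#'
#' Emits the same schema [read_sample_table()] reads, so write/read
#' round-trips are the identity on valid tables.
#'
#' @param t A `sample_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sample_table <- function(t, path) {
  t <- as_sample_table(t)
  utils::write.csv(as.data.frame(t), path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Extract the n-by-9 feature matrix of a sample table
#'
#' @param t A `sample_table`.
#' @return Numeric matrix with feature columns in canonical order and
#'   `sample_id` row names.
#' @export
feature_matrix <- function(t) {
  m <- as.matrix(as.data.frame(t)[, ag_feature_names(), drop = FALSE])
  rownames(m) <- t$sample_id
  m
}

norm_region <- function(x) tolower(trimws(x))

#' Split a sample table by cultivation region
#'
#' Partitions a table into a training table and one or more test tables by
#' region label, mirroring the study design in which models are trained on
#' some producing regions and evaluated on others. Region labels are matched
#' case-insensitively after trimming. Regions assigned to neither group are
#' dropped (the split is exhaustive over assigned regions).
#'
#' @param t A `sample_table`.
#' @param train_regions Character vector of training region labels.
#' @param test_groups List of character vectors, one per test set.
#' @return A list with elements `train` (a `sample_table`) and `tests` (list
#'   of `sample_table`s in the order of `test_groups`).
#' @export
split_by_region <- function(t, train_regions, test_groups = list()) {
  t <- as_sample_table(t)
  groups <- c(list(train_regions), test_groups)
  normed <- lapply(groups, norm_region)
  all_assigned <- unlist(normed)
  if (anyDuplicated(all_assigned)) {
    stop("region groups overlap: ",
         paste(unique(all_assigned[duplicated(all_assigned)]), collapse = ", "),
         call. = FALSE)
  }
  present <- unique(norm_region(t$region))
  unknown <- setdiff(all_assigned, present)
  if (length(unknown) > 0L) {
    stop("assigned region(s) not present in table: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  pick <- function(labels) {
    sub <- t[norm_region(t$region) %in% labels, , drop = FALSE]
    rownames(sub) <- NULL
    class(sub) <- c("sample_table", "data.frame")
    sub
  }
  list(train = pick(normed[[1L]]),
       tests = lapply(normed[-1L], pick))
}

#' Fit a feature standardizer
#'
#' Computes per-feature means and sample standard deviations (n - 1
#' denominator) on a table; [apply_standardizer()] then centres and scales
#' any table with these *fitted* statistics, so test data are always placed
#' in the training set's standardized coordinates.
#'
#' @param t A `sample_table` or a numeric matrix with 9 feature columns.
#' @param fitted_on Provenance tag stored with the standardizer.
#' @return An object of class `ag_standardizer` with elements `means`, `sds`,
#'   `feature_names`, `fitted_on`.
#' @export
fit_standardizer <- function(t, fitted_on = "training") {
  m <- if (is.matrix(t)) t else feature_matrix(t)
  means <- colMeans(m)
  sds <- apply(m, 2L, stats::sd)
  zero <- which(sds == 0 | !is.finite(sds))
  if (length(zero) > 0L) {
    stop("zero-variance feature(s): ",
         paste(colnames(m)[zero], collapse = ", "), call. = FALSE)
  }
  structure(list(means = means, sds = sds,
                 feature_names = colnames(m), fitted_on = fitted_on),
            class = "ag_standardizer")
}

#' Apply (or invert) a fitted standardizer
#'
#' @param s An `ag_standardizer`.
#' @param t A `sample_table` or feature matrix.
#' @return Numeric matrix of standardized features.
#' @export
apply_standardizer <- function(s, t) {
  stopifnot(inherits(s, "ag_standardizer"))
  m <- if (is.matrix(t)) t else feature_matrix(t)
  if (!identical(colnames(m), s$feature_names)) {
    m <- m[, s$feature_names, drop = FALSE]
  }
  sweep(sweep(m, 2L, s$means, "-"), 2L, s$sds, "/")
}

#' @rdname apply_standardizer
#' @param m A standardized matrix to map back to original units.
#' @export
invert_standardizer <- function(s, m) {
  stopifnot(inherits(s, "ag_standardizer"))
  sweep(sweep(m, 2L, s$sds, "*"), 2L, s$means, "+")
}

#' The study's region-based train/test split
#'
#' Training on the Jilin, Liaoning and Shandong samples; test set 1 is
#' Beijing, test set 2 is Shanxi. Applied to the original 106-sample table
#' this yields 64 / 25 / 17 samples.
#'
#' @param t A `sample_table` whose regions use those five labels.
#' @return As [split_by_region()].
#' @export
study_region_split <- function(t) {
  split_by_region(t, train_regions = c("Jilin", "Liaoning", "Shandong"),
                  test_groups = list("Beijing", "Shanxi"))
}
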