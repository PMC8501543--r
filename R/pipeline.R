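#' Default run configuration
#'
#' The study layout: a synthetic cohort (or a user CSV), three training
#' regions with two external test regions, the four default regressors with
#' fivefold cross-validation, and the operating applicability domain at
#' k = 6, Z = 1.6 with the full scan grid.
#'
#' @param output_dir Directory for run artifacts.
#' @param seed Root seed propagated to every stochastic stage.
#' @param input_csv Optional path to a sample-table CSV; when NULL the
#'   default synthetic cohort is generated.
#' @return A `run_config` list.
#' @export
default_run_config <- function(output_dir = tempfile("agrun"), seed = 1L,
                               input_csv = NULL) {
  spec <- default_cohort_spec(seed = seed)
  structure(list(
    input = if (is.null(input_csv)) list(type = "synthetic")
            else list(type = "csv", path = input_csv),
    split = list(
      train_regions = regions_by_role(spec, "train"),
      test_groups = list(regions_by_role(spec, "near_test"),
                         regions_by_role(spec, "shifted_test"))),
    models = list(cv_folds = 5L, grids = list()),
    ad = list(k = 6L, z = 1.6, k_range = c(1L, 12L),
              z_range = c(0.5, 3.0, 0.2)),
    importance_repeats = 10L,
    output_dir = output_dir,
    seed = as.integer(seed)), class = "run_config")
}

#' Read / write a run configuration as YAML
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  validate_run_config(structure(cfg, class = "run_config"))
}

#' @rdname read_run_config
#' @param cfg A `run_config`.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Validate a run configuration
#' @param cfg A `run_config` list.
#' @return `cfg`, invisibly, or an error naming the offending field.
#' @export
validate_run_config <- function(cfg) {
  need <- c("input", "split", "models", "ad", "output_dir", "seed")
  missing <- setdiff(need, names(cfg))
  if (length(missing) > 0L) {
    stop("config missing field(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!cfg$input$type %in% c("synthetic", "csv")) {
    stop("config input.type must be 'synthetic' or 'csv'", call. = FALSE)
  }
  if (identical(cfg$input$type, "csv") && !file.exists(cfg$input$path)) {
    stop("config input.path does not exist: ", cfg$input$path, call. = FALSE)
  }
  if (length(cfg$split$train_regions) == 0L) {
    stop("config split.train_regions is empty", call. = FALSE)
  }
  if (cfg$ad$k < 1L) stop("config ad.k must be >= 1", call. = FALSE)
  invisible(cfg)
}

pipeline_stage <- function(name, out_dir, expr) {
  tryCatch(expr, error = function(e) {
    writeLines(paste0("stage: ", name, "\n", conditionMessage(e)),
               file.path(out_dir, "FAILED"))
    stop("[stage ", name, "] ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the end-to-end age-authentication pipeline
#'
#' Ingests or generates a sample table, splits it by region, writes PCA and
#' age-trend reports, trains the four regressors with grid-search
#' cross-validation, fits the operating applicability domain, scans the
#' (k, Z) grid, and decomposes test errors into in-domain and out-of-domain
#' parts. All artifacts land under `cfg$output_dir` together with a
#' machine-readable manifest (config echo + seed + package version); two
#' runs with the same config produce the same artifacts.
#'
#' @param cfg A `run_config` (see [default_run_config()]).
#' @return Invisibly, a list with the in-memory results (`table`, `split`,
#'   `pca`, `trends`, `models`, `metrics`, `ad`, `scan`, `id_od`, paths).
#' @export
run_pipeline <- function(cfg) {
  validate_run_config(cfg)
  out <- cfg$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  tab <- pipeline_stage("ingest", out, {
    if (identical(cfg$input$type, "csv")) read_sample_table(cfg$input$path)
    else generate_cohort(default_cohort_spec(seed = cfg$seed))
  })
  write_sample_table(tab, file.path(out, "samples.csv"))

  sp <- pipeline_stage("split", out, {
    split_by_region(tab, cfg$split$train_regions, cfg$split$test_groups)
  })
  write_sample_table(sp$train, file.path(out, "train.csv"))
  for (i in seq_along(sp$tests)) {
    write_sample_table(sp$tests[[i]], file.path(out, sprintf("test%d.csv", i)))
  }
  names(sp$tests) <- paste0("test", seq_along(sp$tests))

  pca <- pipeline_stage("pca", out, fit_pca(tab))
  utils::write.csv(
    data.frame(component = seq_along(pca$explained_variance_ratio),
               explained_variance_ratio = pca$explained_variance_ratio),
    file.path(out, "pca_variance.csv"), row.names = FALSE)
  scores <- project_pca(pca, tab, n_components = 3L)
  utils::write.csv(
    data.frame(sample_id = tab$sample_id, region = tab$region,
               PC1 = scores[, 1L], PC2 = scores[, 2L], PC3 = scores[, 3L]),
    file.path(out, "pca_scores.csv"), row.names = FALSE)

  trends <- pipeline_stage("trends", out, trend_report(sp$train))
  utils::write.csv(trends$groups, file.path(out, "trend_groups.csv"),
                   row.names = FALSE)
  if (!is.null(trends$tests)) {
    utils::write.csv(trends$tests, file.path(out, "trend_tests.csv"),
                     row.names = FALSE)
  }

  fits <- pipeline_stage("train", out, {
    train_all_models(sp$train, seed = cfg$seed, grids = cfg$models$grids,
                     cv_folds = cfg$models$cv_folds)
  })
  metrics <- lapply(fits, function(gs) {
    per_test <- lapply(sp$tests, function(tt) evaluate_model(gs$model, tt)$mse)
    c(list(cv_r2 = gs$cv$r2, cv_mse = gs$cv$mse, params = gs$model$params),
      stats::setNames(per_test, paste0(names(per_test), "_mse")))
  })
  jsonlite::write_json(metrics, file.path(out, "model_metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  saveRDS(lapply(fits, `[[`, "model"), file.path(out, "models.rds"))

  imp <- pipeline_stage("importance", out, {
    lapply(fits, function(gs) {
      permutation_importance(gs$model, sp$train,
                             repeats = cfg$importance_repeats, seed = cfg$seed)
    })
  })
  imp_df <- do.call(rbind, lapply(names(imp), function(mn) {
    cbind(model = mn, imp[[mn]])
  }))
  utils::write.csv(imp_df, file.path(out, "permutation_importance.csv"),
                   row.names = FALSE)

  ad <- pipeline_stage("ad", out, fit_ad(sp$train, k = cfg$ad$k, Z = cfg$ad$z))
  saveRDS(ad, file.path(out, "ad_model.rds"))
  decisions <- do.call(rbind, lapply(names(sp$tests), function(tn) {
    sc <- score_query(ad, sp$tests[[tn]])
    data.frame(sample_id = sp$tests[[tn]]$sample_id, test = tn, sc,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(decisions, file.path(out, "ad_decisions.csv"),
                   row.names = FALSE)

  scan <- pipeline_stage("ad-scan", out, {
    ad_scan(sp$train, sp$tests, lapply(fits, `[[`, "model"),
            k_range = seq(cfg$ad$k_range[1L], cfg$ad$k_range[2L]),
            z_range = seq(cfg$ad$z_range[1L], cfg$ad$z_range[2L],
                          by = cfg$ad$z_range[3L]))
  })
  utils::write.csv(scan, file.path(out, "ad_scan.csv"), row.names = FALSE)

  id_od <- pipeline_stage("id-od", out, {
    id_od_report(ad, sp$tests, lapply(fits, `[[`, "model"))
  })
  utils::write.csv(id_od, file.path(out, "id_od_report.csv"), row.names = FALSE)

  manifest <- list(config = unclass(cfg), seed = cfg$seed,
                   package_version = as.character(utils::packageVersion("ginsengAD")),
                   r_version = as.character(getRversion()),
                   n_samples = nrow(tab),
                   created = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(table = tab, split = sp, pca = pca, trends = trends,
                 models = fits, metrics = metrics, importance = imp, ad = ad,
                 scan = scan, id_od = id_od, output_dir = out))
}

#' Predict with an applicability-domain reliability flag
#'
#' Every query receives a prediction and an in/out-of-domain decision;
#' out-of-domain predictions are flagged `"unreliable"`, never suppressed.
#'
#' @param model An `ag_regressor` or path to a saved `models.rds` entry.
#' @param ad An `ad_model` or path to a saved `ad_model.rds`.
#' @param query A `sample_table` or path to a sample-table CSV (ages may be
#'   arbitrary placeholders for unknown queries).
#' @return data.frame: `sample_id, predicted_age, ts, tad, inside,
#'   reliability`.
#' @export
predict_with_ad <- function(model, ad, query) {
  if (is.character(model)) model <- readRDS(model)[[1L]]
  if (is.character(ad)) ad <- readRDS(ad)
  if (is.character(query)) query <- read_sample_table(query)
  stopifnot(inherits(model, "ag_regressor"), inherits(ad, "ad_model"))
  if (!identical(model$standardizer$feature_names,
                 if (is.null(ad$standardizer)) model$standardizer$feature_names
                 else ad$standardizer$feature_names)) {
    stop("model and applicability domain disagree on feature ordering",
         call. = FALSE)
  }
  pred <- stats::predict(model, query)
  sc <- score_query(ad, query)
  data.frame(sample_id = query$sample_id, predicted_age = pred,
             ts = sc$ts, tad = sc$tad, inside = sc$inside,
             reliability = ifelse(sc$inside, "reliable", "unreliable"),
             stringsAsFactors = FALSE)
}
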