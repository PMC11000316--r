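#' Pipeline configuration
#'
#' Describes one reproducible end-to-end run: where the cohort comes from
#' (a CSV on disk or a synthetic spec — exactly one), the stage
#' configurations, and a single global seed that is fanned out
#' deterministically to every stage (fixed per-stage offsets), so stages
#' can be rerun in isolation yet reproduce the chained run exactly.
#'
#' @param input_path cohort CSV path (mutually exclusive with `spec`).
#' @param spec a [synthetic_spec()] (mutually exclusive with `input_path`).
#' @param label_column,id_column column names for [read_feature_table()].
#' @param prep_cfg,sel_cfg,cv_cfg stage configurations; seeds inside them
#'   are overridden by the fan-out of `seed`.
#' @param model_specs named list of [model_spec()]s; must be non-empty.
#' @param holdout_n synthetic hold-out size scored by the voting stage
#'   (ignored when `holdout_path` is given).
#' @param holdout_path optional CSV of labelled hold-out samples.
#' @param uniform_weights use uniform instead of accuracy soft-vote weights.
#' @param seed global integer seed.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(input_path = NULL, spec = NULL,
                            label_column = "Disease", id_column = "Id",
                            prep_cfg = preprocess_config(),
                            sel_cfg = selector_config(),
                            cv_cfg = cv_config(),
                            model_specs = default_model_specs(),
                            holdout_n = 12L, holdout_path = NULL,
                            uniform_weights = FALSE, seed = 1L) {
  if (is.null(input_path) == is.null(spec)) {
    stop("exactly one of input_path or spec must be set")
  }
  if (!length(model_specs)) stop("model_specs must be non-empty")
  seed <- as.integer(seed)
  # deterministic fan-out: each stage draws from its own offset stream
  if (!is.null(spec)) spec$seed <- seed
  sel_cfg$seed <- seed + 101L
  cv_cfg$seed <- seed + 211L
  for (i in seq_along(model_specs)) {
    model_specs[[i]]$seed <- seed + 307L + i
  }
  structure(list(input_path = input_path, spec = spec,
                 label_column = label_column, id_column = id_column,
                 prep_cfg = prep_cfg, sel_cfg = sel_cfg, cv_cfg = cv_cfg,
                 model_specs = model_specs, holdout_n = as.integer(holdout_n),
                 holdout_path = holdout_path,
                 uniform_weights = uniform_weights, seed = seed),
            class = "pipeline_config")
}

log_line <- function(dir, stage, msg) {
  cat(sprintf("[%s] %s\n", stage, msg), file = file.path(dir, "log.txt"),
      append = TRUE)
}

#' Pipeline stages
#'
#' Stage-isolated execution for debugging: each stage reads the previous
#' stage's files from the run directory and writes its own, so chaining
#' `stage_simulate` (or an input CSV) through `stage_vote` reproduces
#' [run_pipeline()] exactly.
#'
#' `stage_simulate` writes `train.csv`, `holdout.csv`, `informative.json`;
#' `stage_preprocess` writes `preprocessed.csv` and `prep_params.rds`;
#' `stage_select` writes `selection.json`; `stage_train` writes
#' `cv_report.json`, `models.rds` and per-model `roc_<model>.csv`;
#' `stage_vote` writes `predictions.csv` and `voting_summary.json`.
#'
#' @param config a [pipeline_config()].
#' @param dir run directory.
#' @return the run directory, invisibly.
#' @name pipeline_stages
NULL

require_artifact <- function(dir, file, stage) {
  path <- file.path(dir, file)
  if (!file.exists(path)) {
    stop(sprintf("stage %s: expected artifact '%s' not found in %s (run the previous stage first)",
                 stage, file, dir))
  }
  path
}

#' @rdname pipeline_stages
#' @export
stage_simulate <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(config$spec)) stop("stage simulate: config has no synthetic spec")
  train <- generate_cohort(config$spec)
  write_feature_table(train, file.path(dir, "train.csv"))
  holdout <- generate_holdout(config$spec, config$holdout_n)
  write_feature_table(holdout, file.path(dir, "holdout.csv"))
  jsonlite::write_json(attr(train, "informative"),
                       file.path(dir, "informative.json"))
  log_line(dir, "simulate", sprintf("%d train / %d holdout samples",
                                    nrow(train$values), nrow(holdout$values)))
  invisible(dir)
}

read_stage_input <- function(config, dir) {
  path <- if (!is.null(config$input_path)) config$input_path else
    require_artifact(dir, "train.csv", "preprocess")
  read_feature_table(path, config$label_column, config$id_column)
}

#' @rdname pipeline_stages
#' @export
stage_preprocess <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  table <- read_stage_input(config, dir)
  prepped <- preprocess(table, config$prep_cfg)
  write_feature_table(prepped, file.path(dir, "preprocessed.csv"))
  saveRDS(attr(prepped, "prep_params"), file.path(dir, "prep_params.rds"))
  log_line(dir, "preprocess",
           sprintf("%d x %d in -> %d x %d out (fold_safe=%s)",
                   nrow(table$values), ncol(table$values),
                   nrow(prepped$values), ncol(prepped$values),
                   isTRUE(config$cv_cfg$fold_safe_preprocessing)))
  invisible(dir)
}

read_preprocessed <- function(config, dir, stage) {
  path <- require_artifact(dir, "preprocessed.csv", stage)
  read_feature_table(path, config$label_column, config$id_column)
}

#' @rdname pipeline_stages
#' @export
stage_select <- function(config, dir) {
  table <- read_preprocessed(config, dir, "select")
  sel <- select_features(table, config$sel_cfg, config$model_specs,
                         config$cv_cfg)
  write_selection_json(sel, file.path(dir, "selection.json"))
  log_line(dir, "select", sprintf("threshold %d, %d features",
                                  sel$chosen_threshold,
                                  length(sel$selected_features)))
  invisible(dir)
}

#' @rdname pipeline_stages
#' @export
stage_train <- function(config, dir) {
  table <- read_preprocessed(config, dir, "train")
  sel_path <- file.path(dir, "selection.json")
  if (file.exists(sel_path)) {
    sel <- jsonlite::read_json(sel_path, simplifyVector = TRUE)
    table <- subset_table(table, NULL, sel$selected_features)
  }
  cv <- cross_validate(table, config$model_specs, config$cv_cfg)
  write_cv_json(cv, file.path(dir, "cv_report.json"))
  models <- lapply(config$model_specs, function(s) fit_final(table, s))
  names(models) <- names(config$model_specs)
  saveRDS(models, file.path(dir, "models.rds"))
  for (m in colnames(cv$oof_prob)) {
    ok <- !is.na(cv$oof_prob[, m])
    rc <- roc_points(table$labels[ok], cv$oof_prob[ok, m])
    utils::write.csv(rc, file.path(dir, paste0("roc_", m, ".csv")),
                     row.names = FALSE)
  }
  log_line(dir, "train", sprintf("best model %s (AUC %.3f)", cv$best_model,
                                 max(cv$summary$mean_auc)))
  invisible(dir)
}

#' @rdname pipeline_stages
#' @export
stage_vote <- function(config, dir) {
  models_path <- require_artifact(dir, "models.rds", "vote")
  models <- readRDS(models_path)
  prep_params <- readRDS(require_artifact(dir, "prep_params.rds", "vote"))
  cvj <- jsonlite::read_json(require_artifact(dir, "cv_report.json", "vote"),
                             simplifyVector = TRUE)
  weights <- vote_weights(
    stats::setNames(cvj$summary$mean_accuracy, cvj$summary$model),
    uniform = isTRUE(config$uniform_weights))
  ho_path <- if (!is.null(config$holdout_path)) config$holdout_path else
    require_artifact(dir, "holdout.csv", "vote")
  holdout <- read_feature_table(ho_path, config$label_column,
                                config$id_column)
  prepped <- apply_preprocess(prep_params, holdout)
  sel_path <- file.path(dir, "selection.json")
  if (file.exists(sel_path)) {
    sel <- jsonlite::read_json(sel_path, simplifyVector = TRUE)
    prepped <- subset_table(prepped, NULL, sel$selected_features)
  }
  preds <- validate_holdout(models, weights, prepped)
  write_prediction_report(preds, file.path(dir, "predictions.csv"))
  summary <- list(n = nrow(preds),
                  hard_correct = count_correct(preds, "hard"),
                  soft_correct = count_correct(preds, "soft"),
                  weights = as.list(round(weights, 10)))
  jsonlite::write_json(summary, file.path(dir, "voting_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  log_line(dir, "vote", sprintf("hard %d/%d, soft %d/%d correct",
                                summary$hard_correct, summary$n,
                                summary$soft_correct, summary$n))
  invisible(dir)
}

#' Run the full pipeline
#'
#' Chains simulate (when configured with a synthetic spec), preprocess,
#' select, train and vote in one run directory, then writes a provenance
#' manifest (`manifest.json`: config digest, seed, package/R versions and
#' the artifact list). Rerunning with the same config and seed reproduces
#' the selection and prediction files byte for byte.
#'
#' @param config a [pipeline_config()].
#' @param dir output run directory (created if needed).
#' @return the run directory, invisibly.
#' @export
run_pipeline <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(config$spec)) stage_simulate(config, dir)
  stage_preprocess(config, dir)
  stage_select(config, dir)
  stage_train(config, dir)
  stage_vote(config, dir)
  cfg_json <- jsonlite::toJSON(config_digestible(config), auto_unbox = TRUE,
                               digits = NA)
  manifest <- list(
    config = jsonlite::fromJSON(cfg_json, simplifyVector = TRUE),
    config_sha = sum(utf8ToInt(cfg_json) * seq_along(utf8ToInt(cfg_json))) %%
      2147483647,
    seed = config$seed,
    package_version = as.character(utils::packageVersion("pepvote")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    artifacts = sort(setdiff(list.files(dir), "manifest.json")))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

# Strip function-free, JSON-friendly view of a config for the manifest.
config_digestible <- function(config) {
  out <- unclass(config)
  out$prep_cfg <- unclass(out$prep_cfg)
  out$sel_cfg <- unclass(out$sel_cfg)
  out$cv_cfg <- unclass(out$cv_cfg)
  out$model_specs <- lapply(out$model_specs, function(s) {
    list(kind = s$kind, seed = s$seed,
         hyperparams = s$hyperparams[!vapply(s$hyperparams, is.null,
                                             logical(1))])
  })
  if (!is.null(out$spec)) out$spec <- unclass(out$spec)
  out[!vapply(out, is.null, logical(1))]
}
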