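#' Fit the consensus-selection voting ensemble
#'
#' The package's top-level fitting function. Given a raw case-control
#' feature table it (i) runs the preprocessing chain (sparse-row/column
#' dropping, categorical encoding, class-conditional mean imputation,
#' min-max scaling); (ii) runs the five feature-ranking methods, scores
#' every feature by how many methods nominated it, and picks the consensus
#' threshold whose restricted feature set maximizes the best model's
#' cross-validated AUC; (iii) cross-validates the five-classifier battery
#' on the selected panel; and (iv) fits each classifier on all samples and
#' derives accuracy-proportional soft-vote weights. The result predicts new
#' cohorts by hard-majority and soft voting.
#'
#' @param table a [feature_table()] (raw; preprocessing is fitted here).
#' @param prep_cfg a [preprocess_config()].
#' @param sel_cfg a [selector_config()].
#' @param model_specs named list of [model_spec()]s
#'   (default [default_model_specs()]).
#' @param cv_cfg a [cv_config()].
#' @param select if `FALSE`, skip feature selection and use every feature.
#' @return an object of class `pepvote` with components `selection`
#'   (`selection_result`), `cv` (`cv_report`), `models`, `weights`,
#'   `prep_params`, `table` (the preprocessed training table restricted to
#'   the selected panel).
#' @seealso [predict.pepvote()], [generate_cohort()]
#' @examples
#' spec <- urine_spec(n_peptides = 40, effect_size_d = 2, seed = 7)
#' fit <- pepvote(generate_cohort(spec),
#'                sel_cfg = selector_config(k_per_method = 8, seed = 7),
#'                cv_cfg = cv_config(k = 5, seed = 7))
#' print(fit)
#' preds <- predict(fit, generate_holdout(spec, 12))
#' count_correct(preds, "hard")
#' @export
pepvote <- function(table, prep_cfg = preprocess_config(),
                    sel_cfg = selector_config(),
                    model_specs = default_model_specs(),
                    cv_cfg = cv_config(), select = TRUE) {
  prepped <- preprocess(table, prep_cfg)
  prep_params <- attr(prepped, "prep_params")
  if (select) {
    selection <- select_features(prepped, sel_cfg, model_specs, cv_cfg)
    panel <- subset_table(prepped, NULL, selection$selected_features)
  } else {
    selection <- NULL
    panel <- prepped
  }
  cv <- cross_validate(panel, model_specs, cv_cfg)
  models <- lapply(model_specs, function(s) fit_final(panel, s))
  names(models) <- names(model_specs)
  weights <- vote_weights(cv)
  structure(list(selection = selection, cv = cv, models = models,
                 weights = weights, prep_params = prep_params,
                 table = panel, model_specs = model_specs,
                 cv_cfg = cv_cfg),
            class = "pepvote")
}

#' @export
print.pepvote <- function(x, ...) {
  cat("pepvote consensus voting ensemble\n")
  cat(sprintf("  training: %d samples, %d selected features\n",
              length(x$table$sample_ids), length(x$table$feature_names)))
  if (!is.null(x$selection)) {
    cat(sprintf("  consensus threshold: >= %d of 5 selection methods\n",
                x$selection$chosen_threshold))
  }
  cat(sprintf("  best model by CV AUC: %s (%.3f)\n", x$cv$best_model,
              max(x$cv$summary$mean_auc)))
  invisible(x)
}

#' @export
summary.pepvote <- function(object, ...) {
  cat("Consensus voting ensemble\n\n")
  if (!is.null(object$selection)) {
    print(object$selection)
    cat("\n")
  }
  print(object$cv)
  cat("\nsoft-vote weights (normalized CV accuracy):\n")
  print(round(object$weights, 4))
  invisible(object)
}

#' Soft-vote weights of a fitted ensemble
#'
#' @param object a `pepvote` fit.
#' @param ... unused.
#' @return named numeric vector of normalized per-model weights.
#' @export
coef.pepvote <- function(object, ...) object$weights

#' Predict a new cohort with the fitted ensemble
#'
#' Replays the stored preprocessing on the new table (global-mean
#' imputation, stored ranges with clipping), restricts to the selected
#' panel, and scores it with all five models plus both voting strategies.
#'
#' @param object a `pepvote` fit.
#' @param newdata a raw [feature_table()] with the training columns.
#' @param ... unused.
#' @return an `ensemble_prediction` (see [validate_holdout()]).
#' @export
predict.pepvote <- function(object, newdata, ...) {
  prepped <- apply_preprocess(object$prep_params, newdata)
  validate_holdout(object$models, object$weights, prepped)
}

#' Plot cross-validated ROC curves of the ensemble members
#'
#' Draws, per model, the empirical ROC of the out-of-fold predictions
#' pooled over the CV folds, with the rank-based AUC in the legend.
#'
#' @param x a `pepvote` fit.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, the list of per-model ROC coordinate frames.
#' @export
plot.pepvote <- function(x, ...) {
  oof <- x$cv$oof_prob
  y <- x$table$labels
  cols <- grDevices::hcl.colors(ncol(oof), "Dark 3")
  graphics::plot(c(0, 1), c(0, 1), type = "l", lty = 3, col = "grey",
                 xlab = "False positive rate", ylab = "True positive rate",
                 main = "Cross-validated ROC", ...)
  curves <- list()
  leg <- character(ncol(oof))
  for (i in seq_len(ncol(oof))) {
    ok <- !is.na(oof[, i])
    rc <- roc_points(y[ok], oof[ok, i])
    graphics::lines(rc$fpr, rc$tpr, col = cols[i], lwd = 2)
    leg[i] <- sprintf("%s (AUC %.2f)", colnames(oof)[i],
                      auc_rank(y[ok], oof[ok, i]))
    curves[[colnames(oof)[i]]] <- rc
  }
  graphics::legend("bottomright", legend = leg, col = cols, lwd = 2,
                   bty = "n")
  invisible(curves)
}
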