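#' Classifier specification
#'
#' One of the five classifier families used by the pipeline, with its
#' hyperparameters. Defaults: logistic regression as a plain binomial GLM;
#' decision tree without a depth cap; KNN with 5 neighbours (Euclidean);
#' SVM with a radial-basis kernel, cost 1 and gamma = 1/n_features,
#' probability-calibrated; random forest with 500 trees.
#'
#' @param kind one of `"LR"`, `"DT"`, `"KNN"`, `"SVM"`, `"RF"`.
#' @param ... hyperparameter overrides: `neighbors` (KNN), `cost` and
#'   `gamma` (SVM; `gamma = NULL` means 1/n_features), `ntree` (RF),
#'   `maxdepth` (DT).
#' @param seed integer seed for the stochastic fits.
#' @return a `model_spec` list.
#' @export
model_spec <- function(kind = c("LR", "DT", "KNN", "SVM", "RF"), ...,
                       seed = 1L) {
  kind <- match.arg(kind)
  hp <- utils::modifyList(
    list(neighbors = 5L, cost = 1, gamma = NULL, ntree = 500L,
         maxdepth = 30L),
    list(...))
  stopifnot(hp$neighbors >= 1, hp$cost > 0,
            is.null(hp$gamma) || hp$gamma > 0)
  structure(list(kind = kind, hyperparams = hp, seed = as.integer(seed)),
            class = "model_spec")
}

#' The default five-classifier battery
#'
#' @param seed base seed; model i uses `seed + i` so their random streams
#'   differ.
#' @return named list of five [model_spec()]s.
#' @export
default_model_specs <- function(seed = 1L) {
  kinds <- c("LR", "DT", "KNN", "SVM", "RF")
  specs <- lapply(seq_along(kinds), function(i) {
    model_spec(kinds[i], seed = seed + i)
  })
  names(specs) <- kinds
  specs
}

#' Cross-validation configuration
#'
#' @param k number of folds (default 10).
#' @param stratified preserve the class ratio per fold (default `TRUE`).
#' @param seed integer seed for the fold shuffle.
#' @param fold_safe_preprocessing refit imputation means and min-max ranges
#'   inside each training fold instead of once on the full table
#'   (default `FALSE`, which matches fitting the preprocessing globally
#'   before CV).
#' @return a `cv_config` list.
#' @export
cv_config <- function(k = 10L, stratified = TRUE, seed = 1L,
                      fold_safe_preprocessing = FALSE) {
  stopifnot(k >= 2)
  structure(list(k = as.integer(k), stratified = stratified,
                 seed = as.integer(seed),
                 fold_safe_preprocessing = fold_safe_preprocessing),
            class = "cv_config")
}

#' Stratified fold assignment
#'
#' Deterministic given the seed. With stratification, samples of each class
#' are shuffled and dealt cyclically into the k folds, the second class
#' continuing the deal where the first stopped — so per-fold class counts
#' differ from exact proportionality by at most one and fold sizes differ
#' by at most one.
#'
#' @param table a [feature_table()].
#' @param config a [cv_config()].
#' @return integer vector of fold ids in `1..k`, one per sample.
#' @export
make_folds <- function(table, config = cv_config()) {
  n <- length(table$sample_ids)
  k <- config$k
  if (k > n) stop("more folds than samples")
  set.seed(config$seed)
  fold <- integer(n)
  if (config$stratified) {
    counter <- 0L
    for (cls in 0:1) {
      idx <- which(table$labels == cls)
      if (length(idx) < k) {
        stop(sprintf(
          "class %d has %d samples, fewer than k = %d folds; reduce k",
          cls, length(idx), k))
      }
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- ((counter + seq_along(idx) - 1L) %% k) + 1L
      counter <- counter + length(idx)
    }
  } else {
    fold <- ((sample.int(n) - 1L) %% k) + 1L
  }
  fold
}

#' Rank-based AUC
#'
#' Area under the ROC curve computed as the Mann-Whitney statistic: the
#' probability that a random positive scores above a random negative, with
#' ties counting one half (so a constant score gives 0.5). Invariant under
#' strictly monotone transforms of the score.
#'
#' @param y_true 0/1 truth vector.
#' @param y_score numeric scores, larger meaning more positive.
#' @return AUC in \[0, 1\].
#' @export
auc_rank <- function(y_true, y_score) {
  pos <- y_true == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("AUC undefined: single-class truth")
  r <- rank(y_score)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Confusion-matrix metrics for a binary classifier
#'
#' With PCa (label 1) as the positive class: Sensitivity = TP/(TP+FN),
#' Specificity = TN/(TN+FP), Accuracy = (TP+TN)/n, F1 = 2TP/(2TP+FP+FN),
#' and rank-based AUC from `y_score` when supplied.
#'
#' @param y_true 0/1 truth vector.
#' @param y_pred 0/1 predicted labels.
#' @param y_score optional scores for the AUC (positive-class probability
#'   or any monotone equivalent).
#' @return named list: `auc` (NA without scores), `accuracy`, `f1`,
#'   `sensitivity`, `specificity`, and the counts `tp, fp, tn, fn`.
#' @export
confusion_metrics <- function(y_true, y_pred, y_score = NULL) {
  stopifnot(length(y_true) == length(y_pred))
  tp <- sum(y_true == 1 & y_pred == 1)
  fn <- sum(y_true == 1 & y_pred == 0)
  tn <- sum(y_true == 0 & y_pred == 0)
  fp <- sum(y_true == 0 & y_pred == 1)
  n <- length(y_true)
  auc <- if (is.null(y_score)) NA_real_ else auc_rank(y_true, y_score)
  list(auc = auc,
       accuracy = (tp + tn) / n,
       f1 = if (2 * tp + fp + fn == 0) NA_real_ else
         2 * tp / (2 * tp + fp + fn),
       sensitivity = if (tp + fn == 0) NA_real_ else tp / (tp + fn),
       specificity = if (tn + fp == 0) NA_real_ else tn / (tn + fp),
       tp = tp, fp = fp, tn = tn, fn = fn)
}

# -- individual model fits ---------------------------------------------------
# Each fit_one returns a handle; predict_one returns positive-class
# probabilities. Seeding happens at fit time so fits are reproducible.

fit_one <- function(spec, x, y) {
  set.seed(spec$seed)
  hp <- spec$hyperparams
  fit <- switch(spec$kind,
    LR = {
      df <- data.frame(x, .y = y, check.names = FALSE)
      suppressWarnings(stats::glm(.y ~ ., data = df,
                                  family = stats::binomial()))
    },
    DT = {
      df <- data.frame(x, .y = factor(y, levels = 0:1), check.names = FALSE)
      rpart::rpart(.y ~ ., data = df, method = "class",
                   control = rpart::rpart.control(maxdepth = hp$maxdepth))
    },
    KNN = list(train = x, cl = factor(y, levels = 0:1),
               k = min(hp$neighbors, nrow(x))),
    SVM = {
      gamma <- if (is.null(hp$gamma)) 1 / ncol(x) else hp$gamma
      e1071::svm(x, factor(y, levels = 0:1), kernel = "radial",
                 cost = hp$cost, gamma = gamma, probability = TRUE)
    },
    RF = randomForest::randomForest(x, factor(y, levels = 0:1),
                                    ntree = hp$ntree))
  structure(list(kind = spec$kind, fit = fit, spec = spec,
                 feature_names = colnames(x)),
            class = "pepvote_model")
}

predict_one <- function(model, x) {
  x <- x[, model$feature_names, drop = FALSE]
  switch(model$kind,
    LR = {
      p <- stats::predict(model$fit, newdata = data.frame(x, check.names = FALSE),
                          type = "response")
      as.numeric(p)
    },
    DT = {
      p <- stats::predict(model$fit, newdata = data.frame(x, check.names = FALSE),
                          type = "prob")
      as.numeric(p[, "1"])
    },
    KNN = {
      set.seed(model$spec$seed)  # knn breaks ties at random
      pr <- class::knn(model$fit$train, x, model$fit$cl, k = model$fit$k,
                       prob = TRUE)
      win <- attr(pr, "prob")
      ifelse(pr == "1", win, 1 - win)
    },
    SVM = {
      set.seed(model$spec$seed)
      p <- stats::predict(model$fit, x, probability = TRUE)
      as.numeric(attr(p, "probabilities")[, "1"])
    },
    RF = as.numeric(stats::predict(model$fit, x, type = "prob")[, "1"]))
}

#' Fit one classifier on a full table
#'
#' Fits the given model on every sample; the handle stores the feature
#' schema and can be reused (including after `saveRDS`/`readRDS`) to
#' predict on new tables preprocessed with the stored training parameters.
#'
#' @param table complete, normalized [feature_table()].
#' @param spec a [model_spec()].
#' @return a `pepvote_model` handle.
#' @export
fit_final <- function(table, spec) {
  fit_one(spec, table$values, table$labels)
}

#' @export
predict.pepvote_model <- function(object, newdata, type = c("prob", "label"),
                                  ...) {
  type <- match.arg(type)
  x <- if (inherits(newdata, "feature_table")) newdata$values else
    as.matrix(newdata)
  p <- predict_one(object, x)
  if (type == "prob") p else as.integer(p >= 0.5)
}

#' Stratified k-fold cross-validation of the classifier battery
#'
#' For every model and fold: fit on the k-1 training folds, score the
#' held-out fold, and compute AUC, Accuracy, F1, Sensitivity and
#' Specificity; per-model means and standard deviations over folds are
#' reported. A fold whose training part is single-class is skipped with a
#' warning and the completed-fold count reported. Deterministic given the
#' seeds.
#'
#' @param table complete, normalized [feature_table()] (or, with
#'   `fold_safe_preprocessing`, an unpreprocessed table plus `prep_cfg`).
#' @param model_specs named list of [model_spec()]s.
#' @param config a [cv_config()].
#' @param prep_cfg a [preprocess_config()], used only when
#'   `config$fold_safe_preprocessing` is `TRUE`: imputation means and
#'   min-max ranges are then refit inside each training fold.
#' @return a `cv_report`: `summary` data.frame (one row per model:
#'   mean/sd of the five metrics, folds completed), `per_fold` raw metric
#'   rows, `best_model` (maximum mean AUC), `folds` assignment, and
#'   per-model out-of-fold `oof_prob` probabilities.
#' @export
cross_validate <- function(table, model_specs = default_model_specs(),
                           config = cv_config(), prep_cfg = NULL) {
  if (is.null(names(model_specs))) {
    names(model_specs) <- vapply(model_specs, `[[`, "", "kind")
  }
  folds <- make_folds(table, config)
  metrics <- c("auc", "accuracy", "f1", "sensitivity", "specificity")
  per_fold <- list()
  oof <- matrix(NA_real_, length(table$sample_ids), length(model_specs),
                dimnames = list(table$sample_ids, names(model_specs)))
  for (f in seq_len(config$k)) {
    test_idx <- which(folds == f)
    train_idx <- which(folds != f)
    if (length(unique(table$labels[train_idx])) < 2) {
      warning(sprintf("fold %d skipped: single-class training data", f))
      next
    }
    if (length(unique(table$labels[test_idx])) < 2) {
      warning(sprintf("fold %d: single-class test fold, AUC undefined", f))
    }
    train <- subset_table(table, train_idx, NULL)
    test <- subset_table(table, test_idx, NULL)
    if (isTRUE(config$fold_safe_preprocessing)) {
      if (is.null(prep_cfg)) prep_cfg <- preprocess_config()
      train <- preprocess(train, prep_cfg)
      test <- apply_preprocess(attr(train, "prep_params"), test)
    }
    for (m in names(model_specs)) {
      spec <- model_specs[[m]]
      spec$seed <- spec$seed + f * 101L  # distinct stream per fold
      model <- fit_one(spec, train$values, train$labels)
      prob <- predict_one(model, test$values)
      oof[test_idx, m] <- prob
      pred <- as.integer(prob >= 0.5)
      cm <- if (length(unique(test$labels)) < 2) {
        c(confusion_metrics(test$labels, pred)[metrics[-1]],
          list(auc = NA_real_))
      } else {
        confusion_metrics(test$labels, pred, prob)
      }
      per_fold[[length(per_fold) + 1L]] <- data.frame(
        model = m, fold = f,
        auc = cm$auc, accuracy = cm$accuracy, f1 = cm$f1,
        sensitivity = cm$sensitivity, specificity = cm$specificity)
    }
  }
  if (!length(per_fold)) stop("no fold completed")
  per_fold <- do.call(rbind, per_fold)
  summ <- do.call(rbind, lapply(names(model_specs), function(m) {
    rows <- per_fold[per_fold$model == m, ]
    out <- data.frame(model = m, folds_completed = nrow(rows))
    for (met in metrics) {
      v <- rows[[met]]
      out[[paste0("mean_", met)]] <- mean(v, na.rm = TRUE)
      out[[paste0("sd_", met)]] <- stats::sd(v[!is.na(v)])
    }
    out
  }))
  best <- summ$model[which.max(summ$mean_auc)]
  structure(list(summary = summ, per_fold = per_fold, best_model = best,
                 folds = folds, oof_prob = oof),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat("stratified cross-validation report\n")
  cols <- c("model", "mean_auc", "mean_accuracy", "mean_f1",
            "mean_sensitivity", "mean_specificity")
  print(cbind(x$summary["model"],
              round(x$summary[cols[-1]], 3)), row.names = FALSE)
  cat("best model by mean AUC:", x$best_model, "\n")
  invisible(x)
}

#' Serialise a CV report to JSON
#'
#' @param report a `cv_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cv_json <- function(report, path) {
  obj <- list(summary = report$summary, best_model = report$best_model,
              per_fold = report$per_fold)
  jsonlite::write_json(obj, path, pretty = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' ROC curve coordinates
#'
#' Empirical ROC points (false-positive rate, true-positive rate) across
#' all score thresholds, suitable for CSV export and plotting; the
#' trapezoidal area under these points equals [auc_rank()].
#'
#' @inheritParams auc_rank
#' @return data.frame with columns `fpr`, `tpr`, `threshold`.
#' @export
roc_points <- function(y_true, y_score) {
  ord <- order(y_score, decreasing = TRUE)
  y <- y_true[ord]; s <- y_score[ord]
  n1 <- sum(y_true == 1); n0 <- sum(y_true == 0)
  tp <- cumsum(y == 1); fp <- cumsum(y == 0)
  keep <- c(s[-1] != s[-length(s)], TRUE)  # one point per distinct threshold
  data.frame(fpr = c(0, fp[keep] / n0), tpr = c(0, tp[keep] / n1),
             threshold = c(Inf, s[keep]))
}
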