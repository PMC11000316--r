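#' Hard (majority) vote
#'
#' The label predicted by the majority of the models. With the standard
#' five-model battery and binary labels a tie is impossible; for an even
#' number of voters an exact split is an error unless a tie-break label is
#' configured.
#'
#' @param per_model_labels 0/1 vector or matrix (samples x models) of
#'   per-model predicted labels.
#' @param tie 0, 1, or NULL (default): the label returned on an exact
#'   split; NULL makes a split an error.
#' @return 0/1 label (vector when a matrix is given).
#' @export
hard_vote <- function(per_model_labels, tie = NULL) {
  if (is.matrix(per_model_labels)) {
    return(apply(per_model_labels, 1, hard_vote, tie = tie))
  }
  stopifnot(all(per_model_labels %in% c(0, 1)))
  ones <- sum(per_model_labels == 1)
  zeros <- length(per_model_labels) - ones
  if (ones == zeros) {
    if (is.null(tie)) stop("hard vote tied and no tie rule configured")
    return(as.integer(tie))
  }
  as.integer(ones > zeros)
}

#' Accuracy-weighted model weights
#'
#' Normalizes per-model weights — by default each model's mean
#' cross-validated accuracy — to sum to one, for use in [soft_vote()].
#'
#' @param report a `cv_report`, or a named numeric vector of raw weights.
#' @param uniform if `TRUE`, ignore accuracies and weight models equally.
#' @return named numeric weights summing to 1.
#' @export
vote_weights <- function(report, uniform = FALSE) {
  w <- if (is.numeric(report)) report else {
    stats::setNames(report$summary$mean_accuracy, report$summary$model)
  }
  if (any(w < 0)) stop("weights must be non-negative")
  if (uniform || sum(w) == 0) w <- stats::setNames(rep(1, length(w)), names(w))
  w / sum(w)
}

#' Soft (probability-weighted) vote
#'
#' The ensemble score is the weighted average of the models' positive-class
#' probabilities, with weights normalized to sum to one; the call is PCa (1)
#' when the score is at least 0.5 (ties break toward the positive class).
#'
#' @param per_model_probs numeric vector, or matrix (samples x models), of
#'   positive-class probabilities in \[0, 1\].
#' @param weights non-negative per-model weights (normalized internally);
#'   default uniform.
#' @return list with `label` (0/1) and `score` (in \[0, 1\]); vectors when a
#'   matrix is given.
#' @export
soft_vote <- function(per_model_probs, weights = NULL) {
  m <- if (is.matrix(per_model_probs)) ncol(per_model_probs) else
    length(per_model_probs)
  if (is.null(weights)) weights <- rep(1, m)
  if (any(per_model_probs < 0 | per_model_probs > 1)) {
    stop("probabilities must lie in [0, 1]")
  }
  w <- vote_weights(weights)
  score <- if (is.matrix(per_model_probs)) {
    as.numeric(per_model_probs %*% w)
  } else {
    sum(per_model_probs * w)
  }
  list(label = as.integer(score >= 0.5), score = score)
}

#' Score a hold-out cohort with the voting ensemble
#'
#' Applies the trained models to a hold-out table (already transformed with
#' the stored training preprocessing), collects per-model labels and
#' probabilities, and combines them by hard-majority and accuracy-weighted
#' soft voting.
#'
#' @param models named list of `pepvote_model` handles (see [fit_final()]).
#' @param weights normalized soft-vote weights (see [vote_weights()]).
#' @param holdout_table a [feature_table()] with the training feature
#'   schema; an error lists any missing/extra features.
#' @return an `ensemble_prediction` data.frame: `patient_id`, `true_label`,
#'   per-model `prob_*` and `pred_*` columns, `hard_vote`, `soft_score`,
#'   `soft_vote`.
#' @export
validate_holdout <- function(models, weights, holdout_table) {
  need <- models[[1]]$feature_names
  have <- holdout_table$feature_names
  if (length(setdiff(need, have))) {
    stop("holdout is missing feature(s): ",
         paste(setdiff(need, have), collapse = ", "))
  }
  n <- length(holdout_table$sample_ids)
  out <- data.frame(patient_id = holdout_table$sample_ids,
                    true_label = holdout_table$labels,
                    stringsAsFactors = FALSE)
  probs <- matrix(NA_real_, n, length(models),
                  dimnames = list(NULL, names(models)))
  if (n > 0) {
    for (m in names(models)) {
      probs[, m] <- predict_one(models[[m]], holdout_table$values)
    }
  }
  preds <- matrix(as.integer(probs >= 0.5), n, length(models),
                  dimnames = dimnames(probs))
  for (m in names(models)) {
    out[[paste0("prob_", m)]] <- probs[, m]
    out[[paste0("pred_", m)]] <- preds[, m]
  }
  if (n > 0) {
    sv <- soft_vote(probs, weights)
    # even user-configured subsets can tie; the tie rule is soft-vote fallback
    out$hard_vote <- vapply(seq_len(n), function(i) {
      hard_vote(preds[i, ], tie = sv$label[i])
    }, integer(1))
    out$soft_score <- sv$score
    out$soft_vote <- sv$label
  } else {
    out$hard_vote <- integer(0)
    out$soft_score <- numeric(0)
    out$soft_vote <- integer(0)
  }
  class(out) <- c("ensemble_prediction", "data.frame")
  out
}

#' Count correct ensemble calls
#'
#' @param preds an `ensemble_prediction` with known true labels.
#' @param strategy `"hard"` or `"soft"`.
#' @return integer count of samples whose ensemble call equals the truth.
#' @export
count_correct <- function(preds, strategy = c("hard", "soft")) {
  strategy <- match.arg(strategy)
  if (is.null(preds$true_label) || anyNA(preds$true_label)) {
    stop("true labels required to count correct predictions")
  }
  call <- if (strategy == "hard") preds$hard_vote else preds$soft_vote
  sum(call == preds$true_label)
}
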