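#' Feature-selector configuration
#'
#' Shared settings for the five ranking methods and the consensus sweep.
#'
#' @param k_per_method number of features each method nominates; default
#'   `max(10, ceiling(n_features / 10))`, resolved at fit time when `NULL`.
#'   Comparable set sizes across methods are what makes the consensus score
#'   meaningful.
#' @param pearson_redundancy_cutoff drop a candidate whose absolute Pearson
#'   correlation with an already-kept feature exceeds this (default 0.9).
#' @param rfe_step features removed per elimination round (default 1).
#' @param rf_ntree trees in the random-forest importance fit (default 500).
#' @param candidate_thresholds consensus thresholds tried by
#'   [sweep_threshold()]; subset of 1:5, default `5:1`.
#' @param seed integer seed for the stochastic selectors (random forest).
#' @return a `selector_config` list.
#' @export
selector_config <- function(k_per_method = NULL,
                            pearson_redundancy_cutoff = 0.9,
                            rfe_step = 1, rf_ntree = 500,
                            candidate_thresholds = 5:1, seed = 1L) {
  stopifnot(pearson_redundancy_cutoff > 0, pearson_redundancy_cutoff <= 1,
            rfe_step >= 1, all(candidate_thresholds %in% 1:5))
  structure(list(k_per_method = k_per_method,
                 pearson_redundancy_cutoff = pearson_redundancy_cutoff,
                 rfe_step = as.integer(rfe_step),
                 rf_ntree = as.integer(rf_ntree),
                 candidate_thresholds = as.integer(candidate_thresholds),
                 seed = as.integer(seed)),
            class = "selector_config")
}

resolve_k <- function(cfg, p) {
  k <- cfg$k_per_method
  if (is.null(k)) k <- max(10, ceiling(p / 10))
  as.integer(min(k, p))
}

#' Pearson correlation matrix of the features
#'
#' The correlation matrix R with entries `R[i,j] = C[i,j] / sqrt(C[i,i] *
#' C[j,j])`, where C is the feature covariance matrix — each entry is the
#' covariance of a feature pair divided by the product of their standard
#' deviations. Constant features, whose standard deviation is zero, get
#' r = 0 against every other feature and 1 on the diagonal, with a warning.
#'
#' @param table a complete (no missing values) [feature_table()] with at
#'   least two samples.
#' @return list with `R` (correlations), `C` (covariances) and
#'   `feature_names`, of class `correlation_matrix`.
#' @export
pearson_matrix <- function(table) {
  x <- table$values
  if (nrow(x) < 2) stop("need at least 2 samples for correlations")
  if (anyNA(x)) stop("missing values present; impute first")
  C <- stats::cov(x)
  s <- sqrt(diag(C))
  const <- s == 0
  if (any(const)) {
    warning("constant feature(s): ",
            paste(table$feature_names[const], collapse = ", "))
    s[const] <- 1
  }
  R <- C / tcrossprod(s)
  R[const, ] <- 0
  R[, const] <- 0
  diag(R) <- 1
  R[] <- pmin(pmax(R, -1), 1)
  structure(list(R = R, C = C, feature_names = table$feature_names),
            class = "correlation_matrix")
}

cor_with_label <- function(table) {
  y <- table$labels
  apply(table$values, 2, function(v) {
    if (stats::sd(v) == 0 || stats::sd(y) == 0) return(0)
    stats::cor(v, y)
  })
}

#' Pearson redundancy-filtered selection
#'
#' Ranks features by absolute Pearson correlation with the diagnosis label,
#' then scans the ranking greedily, discarding any feature whose absolute
#' correlation with an already-kept feature exceeds the redundancy cutoff —
#' so only features with mutually low correlation are kept. If pruning
#' leaves fewer than `k` survivors, the ranking is topped up with the
#' highest-ranked pruned features so every method nominates a comparable
#' set size.
#'
#' @param table complete, normalized [feature_table()].
#' @param cfg a [selector_config()].
#' @return character vector of `k_per_method` feature names.
#' @export
select_pearson <- function(table, cfg = selector_config()) {
  k <- resolve_k(cfg, length(table$feature_names))
  pm <- suppressWarnings(pearson_matrix(table))
  rank_order <- order(-abs(cor_with_label(table)))
  kept <- integer(0)
  for (j in rank_order) {
    if (length(kept) >= k) break
    if (!length(kept) ||
        all(abs(pm$R[j, kept]) <= cfg$pearson_redundancy_cutoff)) {
      kept <- c(kept, j)
    }
  }
  if (length(kept) < k) {
    kept <- c(kept, setdiff(rank_order, kept)[seq_len(k - length(kept))])
  }
  table$feature_names[kept]
}

#' Chi-square statistic of a contingency table
#'
#' Plain `sum((O - E)^2 / E)` without continuity correction. For a matrix,
#' expected counts come from the row/column margins under independence; for
#' a vector, `expected` must be supplied.
#'
#' @param observed matrix or vector of non-negative observed counts.
#' @param expected expected counts (required when `observed` is a vector).
#' @return the chi-square statistic.
#' @export
chi_square_stat <- function(observed, expected = NULL) {
  if (is.matrix(observed) && is.null(expected)) {
    expected <- outer(rowSums(observed), colSums(observed)) / sum(observed)
  }
  if (is.null(expected)) stop("expected counts required for a vector")
  sum((observed - expected)^2 / expected)
}

#' Chi-square feature scoring
#'
#' Scores each non-negative feature by how far its class-wise totals deviate
#' from what independence of feature and diagnosis would predict: observed
#' counts are the per-class sums of the feature, expected counts split the
#' feature total by class frequency. The top `k` features by statistic are
#' selected. Requires non-negative values, which min-max normalization
#' guarantees.
#'
#' @inheritParams select_pearson
#' @return character vector of selected feature names.
#' @export
select_chi2 <- function(table, cfg = selector_config()) {
  x <- table$values
  if (any(x < 0)) {
    stop("negative feature values; run min-max normalization first")
  }
  k <- resolve_k(cfg, ncol(x))
  n <- nrow(x)
  prop <- c(mean(table$labels == 0L), mean(table$labels == 1L))
  stat <- apply(x, 2, function(v) {
    obs <- c(sum(v[table$labels == 0L]), sum(v[table$labels == 1L]))
    exp <- sum(v) * prop
    if (all(exp == 0)) return(0)
    sum((obs - exp)^2 / exp)
  })
  table$feature_names[order(-stat)[seq_len(k)]]
}

# Ridge-logistic coefficient magnitudes used as RFE feature weights.
# glmnet handles the p > n regimes typical of peptide panels; lambda = 1/n
# corresponds to unit-strength L2 regularisation of the mean log-likelihood.
rfe_weights <- function(x, y) {
  fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                        lambda = 1 / nrow(x), standardize = FALSE)
  abs(as.numeric(fit$beta))
}

#' Recursive feature elimination
#'
#' Repeatedly fits a ridge-penalized logistic regression and removes the
#' `rfe_step` features with the smallest absolute coefficients until
#' `k_per_method` remain — pruning the weakest features while colinear
#' blocks shed their redundant members.
#'
#' @inheritParams select_pearson
#' @return character vector of the surviving feature names, with the full
#'   elimination order (first eliminated first) in
#'   `attr(, "elimination_order")`.
#' @export
select_rfe <- function(table, cfg = selector_config()) {
  p <- length(table$feature_names)
  k <- resolve_k(cfg, p)
  if (!is.null(cfg$k_per_method) && cfg$k_per_method > p) {
    stop("k_per_method exceeds number of features")
  }
  alive <- seq_len(p)
  eliminated <- integer(0)
  y <- table$labels
  while (length(alive) > k) {
    w <- rfe_weights(table$values[, alive, drop = FALSE], y)
    n_drop <- min(cfg$rfe_step, length(alive) - k)
    # ties broken toward the later column, keeping earlier features
    drop_local <- order(w, -seq_along(alive))[seq_len(n_drop)]
    eliminated <- c(eliminated, alive[drop_local])
    alive <- alive[-drop_local]
  }
  out <- table$feature_names[alive]
  attr(out, "elimination_order") <- table$feature_names[eliminated]
  out
}

#' Random-forest importance selection
#'
#' Fits a seeded random forest and ranks features by mean impurity-decrease
#' (Gini) importance, normalized to sum to one; the top `k` are selected.
#'
#' @inheritParams select_pearson
#' @return character vector of selected names; normalized importances in
#'   `attr(, "importance")`.
#' @export
select_rf <- function(table, cfg = selector_config()) {
  k <- resolve_k(cfg, length(table$feature_names))
  set.seed(cfg$seed)
  fit <- randomForest::randomForest(
    x = as.data.frame(table$values), y = factor(table$labels, levels = 0:1),
    ntree = cfg$rf_ntree, importance = FALSE)
  imp <- fit$importance[, "MeanDecreaseGini"]
  if (sum(imp) > 0) imp <- imp / sum(imp)
  out <- table$feature_names[order(-imp)[seq_len(k)]]
  names(imp) <- table$feature_names
  attr(out, "importance") <- imp
  out
}

#' L1-penalized logistic-regression selection
#'
#' Fits the lasso-logistic regularization path and picks the first lambda at
#' which at least `k` coefficients are non-zero (or the smallest lambda if
#' the path never reaches `k`); features are ranked by absolute coefficient
#' at that lambda, topped up by order of entry into the path when fewer than
#' `k` are non-zero. The penalty drives redundant features to exactly zero,
#' which is what makes the method a selector.
#'
#' @inheritParams select_pearson
#' @return character vector of selected feature names.
#' @export
select_lr <- function(table, cfg = selector_config()) {
  p <- length(table$feature_names)
  k <- resolve_k(cfg, p)
  x <- table$values
  y <- table$labels
  fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 1,
                        standardize = FALSE, nlambda = 100)
  beta <- as.matrix(fit$beta)
  nnz <- colSums(beta != 0)
  idx <- which(nnz >= k)
  lam <- if (length(idx)) idx[1] else ncol(beta)
  coefs <- abs(beta[, lam])
  # entry order along the path as tie-breaker / top-up
  entry <- apply(beta != 0, 1, function(z) {
    w <- which(z)
    if (length(w)) w[1] else Inf
  })
  ranked <- order(-coefs, entry, seq_len(p))
  table$feature_names[ranked[seq_len(k)]]
}

#' Consensus relevance score
#'
#' For each feature, the number of selection methods (out of the five:
#' `pearson`, `chi2`, `rfe`, `rf`, `lr`) whose selected set contains it —
#' an integer relevance score from 0 to 5.
#'
#' @param per_method_sets named list with all five method sets.
#' @param feature_names full feature universe to score.
#' @return named integer vector of scores in 0..5.
#' @export
consensus_score <- function(per_method_sets, feature_names) {
  methods <- c("pearson", "chi2", "rfe", "rf", "lr")
  missing <- setdiff(methods, names(per_method_sets))
  if (length(missing)) {
    stop("missing method set(s): ", paste(missing, collapse = ", "))
  }
  score <- integer(length(feature_names))
  names(score) <- feature_names
  for (m in methods) {
    score[feature_names %in% per_method_sets[[m]]] <-
      score[feature_names %in% per_method_sets[[m]]] + 1L
  }
  score
}

#' Run all five selectors and score the consensus
#'
#' Applies the Pearson redundancy filter, chi-square scoring, recursive
#' feature elimination, random-forest importance and L1-logistic selection
#' to the same table, and counts for every feature how many methods
#' nominated it.
#'
#' @inheritParams select_pearson
#' @return list with `per_method_sets` and `consensus_score`.
#' @export
run_selectors <- function(table, cfg = selector_config()) {
  sets <- list(pearson = select_pearson(table, cfg),
               chi2 = select_chi2(table, cfg),
               rfe = as.character(select_rfe(table, cfg)),
               rf = as.character(select_rf(table, cfg)),
               lr = select_lr(table, cfg))
  list(per_method_sets = sets,
       consensus_score = consensus_score(sets, table$feature_names))
}

#' Pick the consensus threshold by cross-validated performance
#'
#' For each candidate threshold t, restricts the table to the features whose
#' consensus score is at least t, cross-validates the classifier battery on
#' the restriction, and keeps the threshold that maximizes the best model's
#' mean AUC. Exact ties break toward the higher (stricter) threshold.
#' Thresholds whose feature set is empty are skipped.
#'
#' @param table complete, normalized [feature_table()].
#' @param scores named consensus scores from [run_selectors()].
#' @param candidate_thresholds integer thresholds to try (subset of 1:5).
#' @param model_specs list of [model_spec()]s for the sweep CV.
#' @param cv_config a [cv_config()].
#' @return a `selection_result` list: `per_method_sets` (when supplied via
#'   `attr(scores, "per_method_sets")`), `consensus_score`,
#'   `chosen_threshold`, `selected_features`, and the per-threshold `sweep`
#'   trace (threshold, n_features, best model, best AUC).
#' @export
sweep_threshold <- function(table, scores,
                            candidate_thresholds = 5:1,
                            model_specs = default_model_specs(),
                            cv_config = cv_config()) {
  candidate_thresholds <- sort(unique(as.integer(candidate_thresholds)),
                               decreasing = TRUE)
  rows <- list()
  best <- NULL
  for (t in candidate_thresholds) {
    feats <- names(scores)[scores >= t]
    if (!length(feats)) next
    sub <- subset_table(table, NULL, feats)
    rep <- cross_validate(sub, model_specs, cv_config)
    auc <- max(rep$summary$mean_auc)
    rows[[length(rows) + 1L]] <- data.frame(
      threshold = t, n_features = length(feats),
      best_model = rep$best_model, best_auc = auc)
    # strictly greater: ties keep the earlier (stricter) threshold
    if (is.null(best) || auc > best$auc) {
      best <- list(threshold = t, auc = auc, features = feats)
    }
  }
  if (is.null(best)) stop("every candidate threshold yields an empty set")
  structure(list(
    per_method_sets = attr(scores, "per_method_sets"),
    consensus_score = scores,
    chosen_threshold = best$threshold,
    selected_features = best$features,
    sweep = do.call(rbind, rows)),
    class = "selection_result")
}

#' Consensus feature selection, end to end
#'
#' Convenience wrapper: [run_selectors()] then [sweep_threshold()].
#'
#' @inheritParams select_pearson
#' @inheritParams sweep_threshold
#' @return a `selection_result`.
#' @export
select_features <- function(table, cfg = selector_config(),
                            model_specs = default_model_specs(),
                            cv_config = cv_config()) {
  sel <- run_selectors(table, cfg)
  scores <- sel$consensus_score
  attr(scores, "per_method_sets") <- sel$per_method_sets
  sweep_threshold(table, scores, cfg$candidate_thresholds,
                  model_specs, cv_config)
}

#' @export
print.selection_result <- function(x, ...) {
  cat("consensus feature selection\n")
  cat(sprintf("  chosen threshold: >= %d of 5 methods\n", x$chosen_threshold))
  cat(sprintf("  selected features (%d): %s\n", length(x$selected_features),
              paste(utils::head(x$selected_features, 10), collapse = ", ")))
  if (!is.null(x$sweep)) {
    cat("  sweep trace:\n")
    print(x$sweep, row.names = FALSE)
  }
  invisible(x)
}

#' Serialise a selection result to JSON
#'
#' @param sel a `selection_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_selection_json <- function(sel, path) {
  obj <- list(per_method_sets = sel$per_method_sets,
              consensus_score = as.list(sel$consensus_score),
              chosen_threshold = sel$chosen_threshold,
              selected_features = sel$selected_features)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
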