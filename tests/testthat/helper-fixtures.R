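# Shared fixtures built in code.

example_cohort_path <- function() {
  system.file("extdata", "example_cohort.csv", package = "pepvote")
}

validation_votes_path <- function() {
  system.file("extdata", "urine_validation_votes.csv", package = "pepvote")
}

# Small fully observed table with a known separating feature.
toy_table <- function(n = 40, seed = 1) {
  set.seed(seed)
  labels <- rep(0:1, each = n / 2)
  x <- cbind(signal = labels + stats::rnorm(n, sd = 0.1),
             noise1 = stats::rnorm(n),
             noise2 = stats::rnorm(n))
  feature_table(x, labels)
}

# Deterministic cohort for pipeline-level tests: small but realistic.
small_spec <- function(seed = 11, n_peptides = 30, d = 2) {
  urine_spec(n_pca = 40, n_bph = 40, n_peptides = n_peptides,
             n_informative = 3, effect_size_d = d, seed = seed)
}

# Two-pass covariance oracle, independent of stats::cov.
cov_oracle <- function(x) {
  n <- nrow(x)
  mu <- colMeans(x)
  out <- matrix(0, ncol(x), ncol(x))
  for (i in seq_len(ncol(x))) {
    for (j in seq_len(ncol(x))) {
      out[i, j] <- sum((x[, i] - mu[i]) * (x[, j] - mu[j])) / (n - 1)
    }
  }
  out
}

# Trapezoidal area under the empirical ROC curve.
auc_trapezoid <- function(y_true, y_score) {
  rc <- roc_points(y_true, y_score)
  sum(diff(rc$fpr) * (utils::head(rc$tpr, -1) + utils::tail(rc$tpr, -1)) / 2)
}
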