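test_that("pearson_matrix matches hand values and the covariance oracle", {
  tab <- feature_table(cbind(x = c(1, 2, 3), y = c(2, 4, 6),
                             z = c(6, 4, 2)), c(0, 1, 1))
  pm <- pearson_matrix(tab)
  expect_equal(pm$R["x", "y"], 1)
  expect_equal(pm$R["x", "z"], -1)
  tab2 <- feature_table(cbind(x = c(1, 2, 3, 4), y = c(1, 3, 2, 4)),
                        c(0, 0, 1, 1))
  expect_equal(pearson_matrix(tab2)$R["x", "y"], 0.8)

  set.seed(42)
  for (rep in 1:5) {
    x <- matrix(rnorm(100), 10, 10)
    tab <- feature_table(x, rep(0:1, 5))
    pm <- pearson_matrix(tab)
    C <- cov_oracle(x)
    R <- C / sqrt(outer(diag(C), diag(C)))
    expect_equal(unname(pm$R), unname(R), tolerance = 1e-10)
    expect_equal(pm$R, t(pm$R))
    expect_true(all(abs(pm$R) <= 1 + 1e-12))
  }
  expect_error(pearson_matrix(feature_table(matrix(1, 1, 2), 1)),
               "at least 2 samples")
  const <- feature_table(cbind(a = rep(1, 4), b = 1:4), c(0, 0, 1, 1))
  expect_warning(pmc <- pearson_matrix(const), "constant")
  expect_equal(unname(pmc$R["a", "b"]), 0)
  expect_equal(unname(diag(pmc$R)), c(1, 1))
})

test_that("pearson selector prunes redundant features, keeps k", {
  set.seed(1)
  sig <- rep(0:1, each = 10) + rnorm(20, sd = 0.2)
  tab <- feature_table(cbind(a = sig, b = sig, c = rnorm(20)),
                       rep(0:1, each = 10))
  out <- select_pearson(tab, selector_config(k_per_method = 2))
  expect_equal(out[1], "a")
  expect_false("b" %in% out)     # |r|=1 with a, pruned
  expect_length(out, 2)

  unc <- feature_table(cbind(diag(4), matrix(0.01 * rnorm(8), 4, 2)),
                       c(0, 1, 0, 1))
  expect_length(select_pearson(unc, selector_config(k_per_method = 3)), 3)
})

test_that("chi-square statistic matches printed contingency examples", {
  expect_equal(chi_square_stat(matrix(c(10, 10, 10, 10), 2)), 0)
  expect_equal(chi_square_stat(matrix(c(20, 0, 0, 20), 2)), 40)
  # vector form with explicit expectation
  expect_equal(chi_square_stat(c(20, 0), expected = c(10, 10)), 20)
})

test_that("chi-square selector ranks discriminative features first", {
  set.seed(2)
  y <- rep(0:1, each = 20)
  tab <- feature_table(cbind(flat = rep(0.5, 40), disc = y,
                             noise = runif(40)), y)
  out <- select_chi2(tab, selector_config(k_per_method = 2))
  expect_true("disc" %in% out)
  expect_false("flat" %in% out)
  neg <- feature_table(cbind(x = c(-1, 1, 2, 3)), c(0, 0, 1, 1))
  expect_error(select_chi2(neg), "normalization")
})

test_that("RFE eliminates the weakest feature first, matches refit oracle", {
  set.seed(3)
  y <- rep(0:1, each = 30)
  x <- cbind(s1 = y + rnorm(60, sd = 0.3), s2 = -y + rnorm(60, sd = 0.4),
             junk = rnorm(60))
  tab <- feature_table(apply(x, 2, function(v) (v - min(v)) /
                               (max(v) - min(v))), y)
  out <- select_rfe(tab, selector_config(k_per_method = 2))
  expect_setequal(as.character(out), c("s1", "s2"))
  expect_equal(attr(out, "elimination_order"), "junk")

  # elimination order on a 5-feature toy equals a brute-force oracle that
  # refits the same base estimator after each single removal
  set.seed(4)
  x5 <- matrix(runif(200), 40, 5,
               dimnames = list(NULL, paste0("f", 1:5)))
  y5 <- as.integer(x5[, 2] + 0.5 * x5[, 4] + rnorm(40, sd = 0.3) > 0.8)
  tab5 <- feature_table(x5, y5)
  out5 <- select_rfe(tab5, selector_config(k_per_method = 1))
  alive <- colnames(x5)
  oracle_order <- character(0)
  while (length(alive) > 1) {
    w <- pepvote:::rfe_weights(x5[, alive, drop = FALSE], y5)
    drop <- alive[order(w, -seq_along(alive))[1]]
    oracle_order <- c(oracle_order, drop)
    alive <- setdiff(alive, drop)
  }
  expect_equal(attr(out5, "elimination_order"), oracle_order)
  expect_equal(as.character(out5), alive)

  # k = n_features: identity set
  all5 <- select_rfe(tab5, selector_config(k_per_method = 5))
  expect_setequal(as.character(all5), colnames(x5))
  expect_error(select_rfe(tab5, selector_config(k_per_method = 9)),
               "exceeds")
})

test_that("random-forest importances are normalized and find label copies", {
  set.seed(5)
  y <- rep(0:1, each = 25)
  tab <- feature_table(cbind(copy = y, n1 = runif(50), n2 = runif(50),
                             n3 = runif(50)), y)
  out <- select_rf(tab, selector_config(k_per_method = 1, seed = 5))
  expect_equal(as.character(out), "copy")
  imp <- attr(out, "importance")
  expect_equal(sum(imp), 1, tolerance = 1e-9)
  # same seed, same answer
  out2 <- select_rf(tab, selector_config(k_per_method = 1, seed = 5))
  expect_equal(attr(out2, "importance"), imp)
})

test_that("rf importances are near-uniform under permuted labels", {
  set.seed(6)
  n <- 60
  tab <- feature_table(matrix(runif(n * 20), n, 20), sample(rep(0:1, n / 2)))
  out <- select_rf(tab, selector_config(k_per_method = 5, seed = 6))
  imp <- attr(out, "importance")
  expect_lt(max(imp) / min(imp), 10)  # no feature dominates pure noise
})

test_that("lasso selection finds informative features, zeroes noise", {
  set.seed(7)
  y <- rep(0:1, each = 30)
  noise9 <- matrix(runif(60 * 9), 60, 9,
                   dimnames = list(NULL, paste0("n", 1:9)))
  tab <- feature_table(cbind(hit = y, noise9), y)
  out <- select_lr(tab, selector_config(k_per_method = 1))
  expect_equal(out, "hit")
  expect_length(select_lr(tab, selector_config(k_per_method = 4)), 4)

  # pure noise under the strong end of the penalty path: mostly zeros
  noise <- feature_table(matrix(runif(40 * 10), 40, 10), rep(0:1, 20))
  fit <- glmnet::glmnet(noise$values, noise$labels, family = "binomial",
                        alpha = 1, standardize = FALSE)
  mid <- as.matrix(fit$beta)[, min(10, ncol(fit$beta))]
  expect_gte(sum(mid == 0), 5)
})

test_that("consensus score counts method agreement", {
  feats <- paste0("f", 1:4)
  sets <- list(pearson = c("f1", "f2"), chi2 = c("f1", "f3"),
               rfe = c("f1", "f2"), rf = c("f1", "f4"), lr = c("f1", "f2"))
  sc <- consensus_score(sets, feats)
  expect_equal(unname(sc), c(5L, 3L, 1L, 1L))
  none <- consensus_score(sets, c(feats, "f9"))
  expect_equal(unname(none[["f9"]]), 0L)
  expect_error(consensus_score(sets[-2], feats), "missing method")
  # every method set has exactly min(k, p) elements
  tab <- preprocess(generate_cohort(small_spec(seed = 31)))
  sel <- run_selectors(tab, selector_config(k_per_method = 7, seed = 31))
  expect_true(all(lengths(sel$per_method_sets) == 7))
  expect_true(all(sel$consensus_score >= 0 & sel$consensus_score <= 5))
})

test_that("threshold sweep maximizes best-model AUC, ties break stricter", {
  tab <- preprocess(generate_cohort(small_spec(seed = 41)))
  sel <- run_selectors(tab, selector_config(seed = 41))
  specs <- default_model_specs(seed = 41)[c("LR", "KNN")]
  cvc <- cv_config(k = 5, seed = 41)

  res <- sweep_threshold(tab, sel$consensus_score, 5, specs, cvc)
  expect_equal(res$chosen_threshold, 5L)  # single candidate chosen trivially

  res2 <- sweep_threshold(tab, sel$consensus_score, c(4, 5), specs, cvc)
  expect_s3_class(res2, "selection_result")
  expect_setequal(res2$selected_features,
                  names(sel$consensus_score)[sel$consensus_score >=
                                               res2$chosen_threshold])
  # monotone: lowering the threshold never shrinks the set
  sizes <- vapply(5:1, function(t) sum(sel$consensus_score >= t), 0L)
  expect_true(all(diff(sizes) >= 0))
  # all-empty candidate list errors
  zero <- stats::setNames(integer(3), paste0("f", 1:3))
  expect_error(sweep_threshold(tab, zero, 5, specs, cvc), "empty")
})
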