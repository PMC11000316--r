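test_that("stratified folds are balanced, exhaustive and deterministic", {
  spec <- serum_spec(seed = 1)  # 69 PCa / 74 BPH = 143 samples
  tab <- generate_cohort(spec)
  cfg <- cv_config(k = 10, seed = 9)
  folds <- make_folds(tab, cfg)
  expect_equal(sort(unique(folds)), 1:10)
  sizes <- tabulate(folds, 10)
  expect_equal(sum(sizes), 143)
  expect_true(all(sizes %in% c(14, 15)))
  # per-fold class counts within 1 of proportionality
  for (f in 1:10) {
    pos <- sum(tab$labels[folds == f])
    expect_lte(abs(pos - 69 * sizes[f] / 143), 1)
  }
  expect_identical(folds, make_folds(tab, cfg))           # same seed
  expect_false(identical(folds, make_folds(tab, cv_config(k = 10,
                                                          seed = 10))))
  # leave-one-out: n singleton folds
  small <- toy_table(n = 12)
  loo <- make_folds(small, cv_config(k = 12, stratified = FALSE, seed = 1))
  expect_equal(sort(tabulate(loo, 12)), rep(1L, 12))
  expect_error(make_folds(small, cv_config(k = 8, seed = 1)),
               "fewer than k")
})

test_that("confusion metrics agree with a brute-force count oracle", {
  set.seed(10)
  for (rep in 1:20) {
    n <- sample(10:50, 1)
    y <- c(0, 1, sample(0:1, n - 2, replace = TRUE))  # both classes present
    p <- sample(0:1, n, replace = TRUE)
    s <- runif(n)
    m <- confusion_metrics(y, p, s)
    tp <- 0; tn <- 0; fp <- 0; fn <- 0
    for (i in seq_len(n)) {
      if (y[i] == 1 && p[i] == 1) tp <- tp + 1
      if (y[i] == 0 && p[i] == 0) tn <- tn + 1
      if (y[i] == 0 && p[i] == 1) fp <- fp + 1
      if (y[i] == 1 && p[i] == 0) fn <- fn + 1
    }
    expect_equal(m$accuracy * n, tp + tn)
    expect_equal(m$sensitivity, tp / (tp + fn))
    expect_equal(m$specificity, tn / (tn + fp))
    expect_equal(m$f1, 2 * tp / (2 * tp + fp + fn))
  }
  perfect <- confusion_metrics(c(0, 0, 1, 1), c(0, 0, 1, 1), c(.1, .2, .8, .9))
  expect_equal(unlist(perfect[c("auc", "accuracy", "f1", "sensitivity",
                                "specificity")]),
               c(auc = 1, accuracy = 1, f1 = 1, sensitivity = 1,
                 specificity = 1))
})

test_that("rank AUC equals trapezoidal ROC area and is monotone-invariant", {
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(5:50, 1)
    y <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    s <- round(runif(n), sample(1:3, 1))  # rounding forces ties
    expect_equal(auc_rank(y, s), auc_trapezoid(y, s), tolerance = 1e-10)
    expect_equal(auc_rank(y, exp(3 * s)), auc_rank(y, s))  # monotone map
  }
  expect_equal(auc_rank(c(0, 1, 0, 1), rep(0.3, 4)), 0.5)  # constant score
  expect_error(auc_rank(c(1, 1), c(.1, .2)), "single-class")
})

test_that("rank AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(12)
  y <- sample(0:1, 40, replace = TRUE, prob = c(.4, .6))
  y[1:2] <- 0:1
  s <- rnorm(40)
  ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                        direction = "<")))
  expect_equal(auc_rank(y, s), ref, tolerance = 1e-10)
})

test_that("cross-validation is deterministic and near-perfect on a label copy", {
  set.seed(13)
  y <- rep(0:1, each = 30)
  tab <- feature_table(cbind(copy = y, noise = runif(60)), sample(y))
  tab$labels <- tab$values[, "copy"]  # label-copy feature, shuffled rows
  specs <- default_model_specs(seed = 13)
  cvc <- cv_config(k = 5, seed = 13)
  rep1 <- cross_validate(tab, specs, cvc)
  expect_true(all(rep1$summary$mean_accuracy >= 0.95))
  expect_true(all(rep1$summary$mean_auc >= 0.95))
  rep2 <- cross_validate(tab, specs, cvc)
  expect_equal(rep1$summary, rep2$summary)
  expect_equal(rep1$oof_prob, rep2$oof_prob)
  # report invariants
  expect_true(all(rep1$summary$mean_auc <=
                    max(rep1$summary[rep1$summary$model == rep1$best_model,
                                     "mean_auc"])))
  # two identical specs give identical rows
  twin <- cross_validate(tab, list(A = specs$KNN, B = specs$KNN), cvc)
  a <- twin$summary[twin$summary$model == "A", -1]
  b <- twin$summary[twin$summary$model == "B", -1]
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)
})

test_that("fold-safe preprocessing refits parameters inside each fold", {
  tab <- generate_cohort(small_spec(seed = 51, n_peptides = 10))
  specs <- default_model_specs(seed = 51)["LR"]
  global <- cross_validate(preprocess(tab), specs, cv_config(k = 5, seed = 51))
  safe <- cross_validate(tab, specs,
                         cv_config(k = 5, seed = 51,
                                   fold_safe_preprocessing = TRUE),
                         prep_cfg = preprocess_config())
  expect_s3_class(safe, "cv_report")
  expect_false(identical(global$oof_prob, safe$oof_prob))
})

test_that("final fits are reusable, serializable and deterministic", {
  tab <- preprocess(generate_cohort(small_spec(seed = 61, n_peptides = 8)))
  for (kind in c("LR", "DT", "KNN", "SVM", "RF")) {
    model <- fit_final(tab, model_spec(kind, seed = 61))
    p1 <- predict(model, tab)
    expect_true(all(p1 >= 0 & p1 <= 1))
    # separable training data is classified correctly by flexible models
    if (kind %in% c("DT", "KNN", "RF")) {
      expect_gte(mean(predict(model, tab, type = "label") == tab$labels),
                 0.9)
    }
    path <- withr::local_tempfile(fileext = ".rds")
    saveRDS(model, path)
    expect_equal(predict(readRDS(path), tab), p1)
    refit <- fit_final(tab, model_spec(kind, seed = 61))
    expect_equal(predict(refit, tab), p1)
  }
})
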