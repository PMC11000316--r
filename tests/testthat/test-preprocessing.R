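test_that("drop_sparse removes overly missing samples then features", {
  vals <- rbind(a = c(NA, NA, NA, 1), b = c(1, 2, 3, 4), c = c(NA, 2, 3, 4),
                d = c(1, 2, 3, 4))
  colnames(vals) <- paste0("f", 1:4)
  tab <- feature_table(vals, c(0, 0, 1, 1))
  out <- drop_sparse(tab, preprocess_config(sample_max_missing_frac = 0.5,
                                            feature_max_missing_frac = 0.5))
  expect_setequal(out$sample_ids, c("b", "c", "d"))
  expect_equal(out$feature_names, paste0("f", 1:4))
  expect_match(paste(attr(out, "log"), collapse = ";"), "dropped sample a")

  # example table: max row missing fraction is 1/7, nothing dropped at 0.5
  ex <- read_feature_table(example_cohort_path())
  kept <- drop_sparse(ex, preprocess_config())
  expect_equal(dim(kept), dim(ex))

  # threshold 0 on a fully observed table is the identity
  full <- toy_table()
  expect_equal(drop_sparse(full, preprocess_config(0, 0))$values,
               full$values)
  allmiss <- feature_table(matrix(NA_real_, 2, 2), c(0, 1))
  expect_error(drop_sparse(allmiss, preprocess_config(0.1, 0.1)),
               "all samples dropped")
})

test_that("drop_irrelevant removes named columns, warns on unknown", {
  tab <- toy_table()
  out <- drop_irrelevant(tab, preprocess_config(
    irrelevant_columns = "noise1"))
  expect_equal(out$feature_names, c("signal", "noise2"))
  expect_equal(drop_irrelevant(tab, preprocess_config())$values, tab$values)
  expect_warning(
    out2 <- drop_irrelevant(tab, preprocess_config(
      irrelevant_columns = "previous_surgery")),
    "previous_surgery")
  expect_equal(out2$values, tab$values)
})

test_that("class-conditional imputation reproduces the worked example", {
  tab <- read_feature_table(example_cohort_path())
  imp <- impute_class_mean(tab)
  expect_false(anyNA(imp$values))
  expect_equal(imp$values["id19", "ProstateGlandSize"], 95)
  expect_equal(imp$values["id144", "ProstateGlandSize"], 35)
  expect_equal(imp$values["id142", "ProstateGlandSize"], 35)
  # idempotent, and class means are preserved by construction
  expect_equal(impute_class_mean(imp)$values, imp$values)
  expect_equal(mean(imp$values[imp$labels == 1, "ProstateGlandSize"]), 35)
  # global mode fills with the overall mean instead
  glob <- impute_class_mean(tab, preprocess_config(
    imputation_mode = "global_mean"))
  expect_equal(unname(glob$values["id19", "ProstateGlandSize"]),
               mean(c(95, 20, 50)))
  # no-missing table: identity
  full <- toy_table()
  expect_equal(impute_class_mean(full)$values, full$values)
})

test_that("imputation falls back to global mean for an empty class", {
  vals <- cbind(x = c(NA, 2, 3, 4), y = 1:4)
  tab <- feature_table(vals, c(0, 0, 1, 1))
  tab$values[1, "x"] <- NA
  tab$values[2, "x"] <- NA  # class 0 entirely missing for x
  expect_warning(out <- impute_class_mean(tab), "global mean")
  expect_equal(unname(out$values[1:2, "x"]), c(3.5, 3.5))
  allmiss <- feature_table(cbind(x = c(NA_real_, NA), y = c(1, 2)), c(0, 1))
  expect_error(impute_class_mean(allmiss), "entirely missing")
})

test_that("categorical encoding uses sorted ordinal codes and is replayable", {
  raw <- data.frame(Id = paste0("s", 1:6), num = 1:6,
                    yn = c("no", "yes", "no", "yes", "yes", "no"),
                    abc = c("b", "a", "c", "a", "b", "c"),
                    Disease = rep(c("BPH", "PCa"), 3))
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(raw, path, row.names = FALSE, quote = FALSE)
  tab <- read_feature_table(path, kind_map = c(
    yn = "clinical_categorical", abc = "clinical_categorical"))
  enc <- encode_categoricals(tab)
  expect_equal(unname(enc$values[, "yn"]), c(0, 1, 0, 1, 1, 0))
  expect_equal(unname(enc$values[, "abc"]), c(1, 0, 2, 0, 1, 2))
  expect_equal(unname(enc$values[, "num"]), as.numeric(1:6))  # untouched
  # stored mapping replays on new data; unseen level errors
  new <- tab
  new$categorical_raw$abc[1] <- "zzz"
  expect_error(encode_categoricals(new, encodings = attr(enc, "encodings")),
               "unseen level 'zzz'.*abc")
})

test_that("min-max normalization maps to [0,1] with stored ranges", {
  tab <- impute_class_mean(read_feature_table(example_cohort_path()))
  norm <- minmax_normalize(tab)
  expect_equal(unname(norm$values["id100", "TotalPsa"]),
               (8.94 - 0.07) / (19.71 - 0.07), tolerance = 1e-4)
  expect_true(all(norm$values >= 0 & norm$values <= 1))

  const <- feature_table(cbind(c = rep(2, 4), x = c(0, 1, 0, 1)),
                         c(0, 0, 1, 1))
  nc <- minmax_normalize(const)
  expect_equal(unname(nc$values[, "c"]), rep(0, 4))   # constant -> 0
  expect_equal(unname(nc$values[, "x"]), c(0, 1, 0, 1))  # already 0/1

  # held-out transform uses training ranges and clips
  ranges <- attr(norm, "ranges")
  probe <- tab
  probe$values["id100", "TotalPsa"] <- 100  # beyond training max
  clipped <- minmax_normalize(probe, ranges = ranges)
  expect_equal(unname(clipped$values["id100", "TotalPsa"]), 1)
  expect_error(minmax_normalize(read_feature_table(example_cohort_path())),
               "impute")
})

test_that("full chain leaves no missing values, everything in [0,1]", {
  tab <- generate_cohort(small_spec(seed = 21))
  out <- preprocess(tab)
  expect_false(anyNA(out$values))
  expect_true(all(out$values >= 0 & out$values <= 1))
  # replaying the stored parameters on the same labelled data is exact
  replay <- apply_preprocess(attr(out, "prep_params"), tab,
                             use_labels = TRUE)
  expect_equal(replay$values, out$values)
  # unlabeled-style replay differs only where class means differ
  deploy <- apply_preprocess(attr(out, "prep_params"), tab)
  obs <- !is.na(tab$values)
  expect_equal(deploy$values[obs], out$values[obs])
})
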