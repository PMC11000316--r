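#' Preprocessing configuration
#'
#' Controls the data-preparation chain applied before feature selection:
#' dropping sparse rows/columns, removing irrelevant columns,
#' class-conditional mean imputation, ordinal encoding of categoricals and
#' min-max scaling to \[0, 1\].
#'
#' @param sample_max_missing_frac drop a sample when more than this fraction
#'   of its cells is missing (default 0.5).
#' @param feature_max_missing_frac drop a feature when more than this
#'   fraction of its cells is missing (default 0.5).
#' @param irrelevant_columns character vector of columns to remove outright
#'   (e.g. free-text notes on previous surgery or biopsy).
#' @param imputation_mode `"class_conditional_mean"` (default): a missing
#'   cell is replaced by the mean of the same feature within the same
#'   diagnosis class; `"global_mean"`: mean over all samples.
#' @param normalize logical, min-max scale numeric features to \[0, 1\]
#'   (default `TRUE`).
#' @param max_categorical_levels sanity cap on distinct levels of a
#'   categorical column (default 20).
#' @return a `preprocess_config` list.
#' @export
preprocess_config <- function(sample_max_missing_frac = 0.5,
                              feature_max_missing_frac = 0.5,
                              irrelevant_columns = character(),
                              imputation_mode = c("class_conditional_mean",
                                                  "global_mean"),
                              normalize = TRUE,
                              max_categorical_levels = 20) {
  imputation_mode <- match.arg(imputation_mode)
  stopifnot(sample_max_missing_frac >= 0, sample_max_missing_frac <= 1,
            feature_max_missing_frac >= 0, feature_max_missing_frac <= 1)
  structure(list(sample_max_missing_frac = sample_max_missing_frac,
                 feature_max_missing_frac = feature_max_missing_frac,
                 irrelevant_columns = as.character(irrelevant_columns),
                 imputation_mode = imputation_mode,
                 normalize = normalize,
                 max_categorical_levels = max_categorical_levels),
            class = "preprocess_config")
}

append_log <- function(table, msg) {
  attr(table, "log") <- c(attr(table, "log"), msg)
  table
}

#' Drop samples and features with too many missing cells
#'
#' Removes first the samples whose missing fraction exceeds
#' `cfg$sample_max_missing_frac`, then the features whose missing fraction
#' (over the remaining samples) exceeds `cfg$feature_max_missing_frac`.
#' Order of the survivors is preserved; a log of what was dropped is kept in
#' `attr(, "log")`.
#'
#' @param table a [feature_table()].
#' @param cfg a [preprocess_config()].
#' @return the filtered feature table.
#' @export
drop_sparse <- function(table, cfg = preprocess_config()) {
  log <- attr(table, "log")
  miss <- is.na(table$values)
  row_frac <- rowMeans(miss)
  keep_rows <- row_frac <= cfg$sample_max_missing_frac
  if (!any(keep_rows)) stop("all samples dropped by missingness filter")
  if (any(!keep_rows)) {
    log <- c(log, sprintf(
      "dropped sample %s: missing fraction %.2f > %.2f",
      table$sample_ids[!keep_rows], row_frac[!keep_rows],
      cfg$sample_max_missing_frac))
  }
  col_frac <- colMeans(miss[keep_rows, , drop = FALSE])
  keep_cols <- col_frac <= cfg$feature_max_missing_frac
  if (any(!keep_cols)) {
    log <- c(log, sprintf(
      "dropped feature %s: missing fraction %.2f > %.2f",
      table$feature_names[!keep_cols], col_frac[!keep_cols],
      cfg$feature_max_missing_frac))
  }
  out <- subset_table(table, which(keep_rows), which(keep_cols))
  attr(out, "log") <- log
  out
}

#' Remove columns considered irrelevant
#'
#' Removes the named columns (e.g. previous-surgery or previous-biopsy
#' notes). Names not present in the table produce a warning, not an error.
#'
#' @inheritParams drop_sparse
#' @return the filtered feature table.
#' @export
drop_irrelevant <- function(table, cfg = preprocess_config()) {
  cols <- cfg$irrelevant_columns
  unknown <- setdiff(cols, table$feature_names)
  if (length(unknown)) {
    warning("irrelevant column(s) not in table: ",
            paste(unknown, collapse = ", "))
  }
  drop <- intersect(cols, table$feature_names)
  if (!length(drop)) return(table)
  out <- subset_table(table, NULL, which(!table$feature_names %in% drop))
  attr(out, "log") <- c(attr(table, "log"),
                        paste("dropped irrelevant column:", drop))
  out
}

# Fit imputation means: per (feature, class) and global per feature.
fit_imputation <- function(table, cfg) {
  vals <- table$values
  cls <- table$labels
  class_means <- rbind(
    colMeans(vals[cls == 0L, , drop = FALSE], na.rm = TRUE),
    colMeans(vals[cls == 1L, , drop = FALSE], na.rm = TRUE))
  global_means <- colMeans(vals, na.rm = TRUE)
  if (any(is.nan(global_means))) {
    stop("feature(s) entirely missing: ",
         paste(table$feature_names[is.nan(global_means)], collapse = ", "))
  }
  list(class_means = class_means, global_means = global_means,
       mode = cfg$imputation_mode)
}

impute_with <- function(table, imp, use_labels = TRUE) {
  vals <- table$values
  miss <- is.na(vals)
  if (!any(miss)) return(table)
  for (j in which(colSums(miss) > 0)) {
    rows <- which(miss[, j])
    if (imp$mode == "class_conditional_mean" && use_labels) {
      fill <- imp$class_means[table$labels[rows] + 1L, j]
      nan <- is.nan(fill)
      if (any(nan)) {
        warning(sprintf(
          "feature '%s': class entirely missing, falling back to global mean",
          table$feature_names[j]))
        fill[nan] <- imp$global_means[j]
      }
    } else {
      fill <- rep(imp$global_means[j], length(rows))
    }
    vals[rows, j] <- fill
  }
  out <- table
  out$values <- vals
  out
}

#' Impute missing numeric cells by class-conditional means
#'
#' Each missing cell of a numeric feature is replaced by the mean of the
#' non-missing values of that feature within the same diagnosis class
#' (default), or over all samples in `global_mean` mode. A (feature, class)
#' pair with no observed value falls back to the global feature mean with a
#' warning; a feature with no observed value at all is an error. The
#' operation is idempotent and preserves the observed class means of each
#' imputed feature.
#'
#' @inheritParams drop_sparse
#' @return the completed feature table.
#' @export
impute_class_mean <- function(table, cfg = preprocess_config()) {
  imp <- fit_imputation(table, cfg)
  out <- impute_with(table, imp)
  append_log(out, sprintf("imputed %d missing cell(s) [%s]",
                          sum(is.na(table$values)), imp$mode))
}

#' Encode categorical features as integer codes
#'
#' Maps each clinical-categorical feature to ordinal integer codes
#' `0..(levels - 1)` in sorted level order, storing the mapping in
#' `attr(, "encodings")` so held-out data can be transformed identically.
#'
#' @inheritParams drop_sparse
#' @param encodings optional previously fitted encodings (named list of
#'   character level vectors); an unseen level at transform time is an
#'   error naming the level and column.
#' @return feature table with categorical columns filled with codes.
#' @export
encode_categoricals <- function(table, cfg = preprocess_config(),
                                encodings = NULL) {
  cat_cols <- names(table$categorical_raw)
  fitted <- list()
  for (col in cat_cols) {
    raw <- table$categorical_raw[[col]]
    levels <- if (!is.null(encodings)) {
      if (is.null(encodings[[col]])) stop("no stored encoding for ", col)
      encodings[[col]]
    } else {
      lv <- sort(unique(raw[!is.na(raw)]))
      if (length(lv) > cfg$max_categorical_levels) {
        stop(sprintf("categorical '%s' has %d levels (cap %d)", col,
                     length(lv), cfg$max_categorical_levels))
      }
      lv
    }
    code <- match(raw, levels) - 1L
    unseen <- which(!is.na(raw) & is.na(code))
    if (length(unseen)) {
      stop(sprintf("unseen level '%s' in column '%s'", raw[unseen[1]], col))
    }
    table$values[, col] <- as.numeric(code)
    fitted[[col]] <- levels
  }
  table$categorical_raw <- list()
  attr(table, "encodings") <- fitted
  table
}

fit_ranges <- function(values) {
  list(min = apply(values, 2, min), max = apply(values, 2, max))
}

apply_ranges <- function(values, ranges, clip = TRUE) {
  span <- ranges$max - ranges$min
  out <- sweep(values, 2, ranges$min)
  const <- span == 0
  span[const] <- 1            # constant feature maps to 0
  out <- sweep(out, 2, span, "/")
  out[, const] <- 0
  if (clip) out[] <- pmin(pmax(out, 0), 1)
  out
}

#' Min-max normalize all features to \[0, 1\]
#'
#' Scales each feature by `(x - min)/(max - min)` using ranges fitted on the
#' given (training) table; constant features map to 0. The fitted ranges are
#' attached as `attr(, "ranges")` for reuse on held-out data, where
#' transformed values are clipped to \[0, 1\]. Requires a complete table
#' (run after imputation).
#'
#' @inheritParams drop_sparse
#' @param ranges optional previously fitted ranges (`list(min=, max=)`);
#'   when supplied, values are transformed with them and clipped.
#' @return normalized feature table with `attr(, "ranges")`.
#' @export
minmax_normalize <- function(table, ranges = NULL) {
  if (anyNA(table$values)) {
    stop("missing values present; impute before normalizing")
  }
  clip <- !is.null(ranges)
  if (is.null(ranges)) ranges <- fit_ranges(table$values)
  table$values <- apply_ranges(table$values, ranges, clip = clip)
  attr(table, "ranges") <- ranges
  table
}

#' Run the full preprocessing chain
#'
#' Applies, in order: irrelevant-column removal, sparse row/column dropping,
#' categorical encoding, mean imputation and (optionally) min-max scaling.
#' The fitted parameters (encodings, imputation means, ranges) are returned
#' so exactly the same transform can be replayed on held-out samples with
#' [apply_preprocess()] — where labels are unknown, imputation falls back to
#' the global training means.
#'
#' @inheritParams drop_sparse
#' @return the transformed feature table with attribute `"prep_params"`.
#' @export
preprocess <- function(table, cfg = preprocess_config()) {
  out <- drop_irrelevant(table, cfg)
  out <- drop_sparse(out, cfg)
  out <- encode_categoricals(out, cfg)
  encodings <- attr(out, "encodings")
  imp <- fit_imputation(out, cfg)
  out <- impute_with(out, imp)
  ranges <- NULL
  if (cfg$normalize) {
    ranges <- fit_ranges(out$values)
    out$values <- apply_ranges(out$values, ranges, clip = FALSE)
  }
  attr(out, "prep_params") <- list(cfg = cfg, encodings = encodings,
                                   imputation = imp, ranges = ranges,
                                   feature_names = out$feature_names)
  out
}

#' Replay fitted preprocessing on new data
#'
#' Transforms a held-out feature table with parameters fitted by
#' [preprocess()]: stored encodings, global-mean imputation (class labels
#' are not assumed available at prediction time), and stored min-max ranges
#' with clipping to \[0, 1\].
#'
#' @param params the `"prep_params"` attribute of a preprocessed table.
#' @param table the new [feature_table()]; must contain every training
#'   feature.
#' @param use_labels if `TRUE`, trust the table's labels and impute
#'   class-conditionally as during training (useful for replaying the fit on
#'   labelled data); default `FALSE`, the deployment setting.
#' @return the transformed table.
#' @export
apply_preprocess <- function(params, table, use_labels = FALSE) {
  missing_feats <- setdiff(params$feature_names, table$feature_names)
  if (length(missing_feats)) {
    stop("holdout table lacks feature(s): ",
         paste(missing_feats, collapse = ", "))
  }
  out <- subset_table(table, NULL, params$feature_names)
  out <- encode_categoricals(out, params$cfg, encodings = params$encodings)
  out <- impute_with(out, params$imputation, use_labels = use_labels)
  if (!is.null(params$ranges)) {
    out$values <- apply_ranges(out$values, params$ranges, clip = TRUE)
  }
  out
}
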