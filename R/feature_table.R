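#' Clinical + peptide feature tables
#'
#' A `feature_table` holds one case-control cohort: a samples x features
#' numeric matrix (peptide intensities plus clinical covariates), per-feature
#' kind tags, and a binary diagnosis label. Missing cells are `NA` internally;
#' on disk they are written as the `NaN` literal. Labels are encoded
#' BPH = 0 (benign control) and PCa = 1 (cancer case, the positive class),
#' and the encoding travels with the object so every downstream stage agrees
#' on it.
#'
#' @param values numeric matrix, samples in rows, features in columns.
#' @param labels integer vector of 0/1 labels (0 = BPH, 1 = PCa), or a
#'   character vector of class names that will be encoded.
#' @param sample_ids character vector of unique sample identifiers. Defaults
#'   to rownames of `values` or `s1..sn`.
#' @param feature_kinds character vector with one of
#'   `"clinical_numeric"`, `"clinical_categorical"`, `"peptide"` per feature.
#'   Defaults to `"peptide"` for every feature.
#' @param categorical_raw named list of character vectors holding the raw
#'   (unencoded) levels of clinical-categorical columns; their cells in
#'   `values` stay `NA` until [encode_categoricals()] assigns integer codes.
#' @return an object of class `feature_table`.
#' @seealso [read_feature_table()], [column_stats()], [preprocess()]
#' @export
feature_table <- function(values, labels, sample_ids = NULL,
                          feature_kinds = NULL, categorical_raw = list()) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  n <- nrow(values)
  p <- ncol(values)
  if (is.null(sample_ids)) {
    sample_ids <- rownames(values)
    if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(n))
  }
  sample_ids <- as.character(sample_ids)
  feature_names <- colnames(values)
  if (is.null(feature_names)) {
    feature_names <- paste0("f", seq_len(p))
    colnames(values) <- feature_names
  }
  if (is.null(feature_kinds)) feature_kinds <- rep("peptide", p)
  if (length(sample_ids) != n) stop("sample_ids length must match rows")
  if (length(feature_kinds) != p) stop("feature_kinds length must match columns")
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample id(s): ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  if (anyDuplicated(feature_names)) stop("duplicate feature name(s)")
  bad_kind <- setdiff(feature_kinds,
                      c("clinical_numeric", "clinical_categorical", "peptide"))
  if (length(bad_kind)) stop("unknown feature kind: ", bad_kind[1])
  labels <- encode_labels(labels)
  if (length(labels) != n) stop("labels length must match rows")
  rownames(values) <- sample_ids
  names(feature_kinds) <- feature_names
  structure(
    list(sample_ids = sample_ids,
         feature_names = feature_names,
         feature_kinds = feature_kinds,
         values = values,
         labels = labels,
         label_encoding = c(BPH = 0L, PCa = 1L),
         categorical_raw = categorical_raw),
    class = "feature_table")
}

# Case-insensitive normalisation of diagnosis labels ("PCA", "pca", "PCa" all
# map to PCa = 1). Anything else is a data error, never a third class.
encode_labels <- function(labels) {
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) stop("numeric labels must be 0/1")
    return(as.integer(labels))
  }
  key <- tolower(trimws(as.character(labels)))
  out <- ifelse(key == "bph", 0L, ifelse(key == "pca", 1L, NA_integer_))
  if (anyNA(out)) {
    bad <- which(is.na(out))[1]
    stop(sprintf("unknown label value '%s' at row %d (expected BPH or PCa)",
                 labels[bad], bad))
  }
  out
}

#' @export
print.feature_table <- function(x, ...) {
  tab <- table(factor(x$labels, levels = 0:1, labels = c("BPH", "PCa")))
  cat(sprintf("feature_table: %d samples x %d features\n",
              length(x$sample_ids), length(x$feature_names)))
  cat(sprintf("  classes: BPH=%d PCa=%d\n", tab[["BPH"]], tab[["PCa"]]))
  kinds <- table(x$feature_kinds)
  cat("  kinds:", paste(names(kinds), kinds, sep = "=", collapse = " "), "\n")
  miss <- sum(is.na(x$values))
  cat(sprintf("  missing cells: %d (%.1f%%)\n", miss,
              100 * miss / length(x$values)))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

# Row/column subsetting that keeps all metadata aligned.
subset_table <- function(table, rows = NULL, cols = NULL) {
  if (is.null(rows)) rows <- seq_along(table$sample_ids)
  if (is.null(cols)) cols <- seq_along(table$feature_names)
  if (is.character(cols)) cols <- match(cols, table$feature_names)
  keep_names <- table$feature_names[cols]
  feature_table(table$values[rows, cols, drop = FALSE],
                labels = table$labels[rows],
                sample_ids = table$sample_ids[rows],
                feature_kinds = unname(table$feature_kinds[cols]),
                categorical_raw = lapply(
                  table$categorical_raw[intersect(names(table$categorical_raw),
                                                  keep_names)],
                  function(v) v[rows]))
}

#' Names of the standard clinical covariates
#'
#' The clinical block of a prostate case-control export: patient age,
#' prostate gland volume (ml), total and free serum PSA (mg/l) and their
#' free/total ratio. Columns with these names are tagged `clinical_numeric`
#' by [read_feature_table()]; everything else (besides id/label) is treated
#' as a peptide intensity.
#' @return character vector of column names.
#' @export
default_clinical_columns <- function() {
  c("Age", "ProstateGlandSize", "TotalPsa", "PsaFree", "FTratio")
}

#' Read a cohort CSV into a feature table
#'
#' Reads the delimited export dialect used for clinical + peptide cohorts:
#' one sample per row, a header, an id column, a diagnosis column with
#' case-insensitive `BPH`/`PCa` values, and `NaN` (any casing) or empty
#' cells for missing values.
#'
#' @param path file path of the delimited text file.
#' @param label_column,id_column names of the diagnosis and identifier
#'   columns (defaults `"Disease"` and `"Id"`).
#' @param clinical_columns columns tagged `clinical_numeric`; defaults to
#'   [default_clinical_columns()].
#' @param kind_map optional named character vector overriding the kind of
#'   individual columns, e.g. `c(previous_surgery = "clinical_categorical")`.
#' @param sep field delimiter, default comma.
#' @return a [feature_table()].
#' @export
read_feature_table <- function(path, label_column = "Disease",
                               id_column = "Id",
                               clinical_columns = default_clinical_columns(),
                               kind_map = NULL, sep = ",") {
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE, quote = "\"",
                           comment.char = "")
  for (need in c(label_column, id_column)) {
    if (!need %in% names(raw)) stop("column not found in file: ", need)
  }
  ids <- trimws(raw[[id_column]])
  if (anyDuplicated(ids)) {
    stop("duplicate sample id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  labels <- encode_labels(raw[[label_column]])
  feat_cols <- setdiff(names(raw), c(label_column, id_column))
  kinds <- ifelse(feat_cols %in% clinical_columns, "clinical_numeric",
                  "peptide")
  names(kinds) <- feat_cols
  if (!is.null(kind_map)) kinds[names(kind_map)] <- kind_map
  n <- nrow(raw)
  values <- matrix(NA_real_, n, length(feat_cols),
                   dimnames = list(ids, feat_cols))
  categorical_raw <- list()
  for (j in seq_along(feat_cols)) {
    col <- feat_cols[j]
    cell <- trimws(raw[[col]])
    miss <- tolower(cell) %in% c("nan", "na", "")
    if (kinds[[col]] == "clinical_categorical") {
      cell[miss] <- NA_character_
      categorical_raw[[col]] <- cell
      next
    }
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(!miss & is.na(num))
    if (length(bad)) {
      stop(sprintf("non-numeric value '%s' in column '%s', row %d",
                   cell[bad[1]], col, bad[1]))
    }
    num[miss] <- NA_real_
    values[, j] <- num
  }
  feature_table(values, labels, sample_ids = ids,
                feature_kinds = unname(kinds),
                categorical_raw = categorical_raw)
}

#' Write a feature table back to the cohort CSV dialect
#'
#' Inverse of [read_feature_table()]: missing cells become the `NaN`
#' literal, labels are written as `BPH`/`PCa`. `read(write(x))` reproduces
#' `x` up to float formatting (values are printed with 15 significant
#' digits).
#'
#' @param table a [feature_table()].
#' @param path output file path.
#' @param sep field delimiter, default comma.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path, sep = ",") {
  df <- data.frame(Id = table$sample_ids, check.names = FALSE,
                   stringsAsFactors = FALSE)
  for (j in seq_along(table$feature_names)) {
    fname <- table$feature_names[j]
    if (table$feature_kinds[[fname]] == "clinical_categorical" &&
        fname %in% names(table$categorical_raw)) {
      cell <- table$categorical_raw[[fname]]
      cell[is.na(cell)] <- "NaN"
    } else {
      v <- table$values[, j]
      cell <- formatC(v, format = "g", digits = 15)
      cell[is.na(v)] <- "NaN"
    }
    df[[fname]] <- cell
  }
  df[["Disease"]] <- c("BPH", "PCa")[table$labels + 1L]
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Per-class summary statistics of one feature
#'
#' Computes, separately for the BPH and PCa class, the mean, standard
#' deviation, minimum, quartiles and maximum of a numeric feature over its
#' non-missing cells — the per-class summary used to describe clinical
#' covariates of a cohort.
#'
#' @param table a [feature_table()].
#' @param feature feature name.
#' @return data.frame with rows `BPH` and `PCa` and columns
#'   `mean, sd, min, q25, q50, q75, max, n`.
#' @export
column_stats <- function(table, feature) {
  j <- match(feature, table$feature_names)
  if (is.na(j)) stop("unknown feature: ", feature)
  out <- lapply(c(BPH = 0L, PCa = 1L), function(cls) {
    v <- table$values[table$labels == cls, j]
    v <- v[!is.na(v)]
    if (!length(v)) {
      stop(sprintf("all values of '%s' missing for class %s", feature,
                   if (cls == 0L) "BPH" else "PCa"))
    }
    q <- stats::quantile(v, c(.25, .5, .75), names = FALSE)
    data.frame(mean = mean(v), sd = if (length(v) > 1) stats::sd(v) else 0,
               min = min(v), q25 = q[1], q50 = q[2], q75 = q[3],
               max = max(v), n = length(v))
  })
  res <- do.call(rbind, out)
  rownames(res) <- c("BPH", "PCa")
  res
}

#' Write an ensemble prediction report
#'
#' Serialises per-sample ensemble calls as a CSV with columns
#' `PatientId, DiagnosedDisease, SoftVoting, HardVoting` — the standard
#' validation-report shape, round-trippable via
#' [read_prediction_report()].
#'
#' @param preds an `ensemble_prediction` (see [validate_holdout()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_prediction_report <- function(preds, path) {
  if (!nrow(preds)) stop("empty prediction set")
  df <- data.frame(
    PatientId = preds$patient_id,
    DiagnosedDisease = c("BPH", "PCa")[preds$true_label + 1L],
    SoftVoting = preds$soft_vote,
    HardVoting = preds$hard_vote)
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an ensemble prediction report
#'
#' @param path CSV written by [write_prediction_report()] (or transcribed in
#'   that shape).
#' @return an `ensemble_prediction` data.frame with columns
#'   `patient_id, true_label, soft_vote, hard_vote`.
#' @export
read_prediction_report <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(PatientId = "character"))
  out <- data.frame(
    patient_id = df$PatientId,
    true_label = encode_labels(df$DiagnosedDisease),
    soft_vote = as.integer(df$SoftVoting),
    hard_vote = as.integer(df$HardVoting),
    stringsAsFactors = FALSE)
  class(out) <- c("ensemble_prediction", "data.frame")
  out
}
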