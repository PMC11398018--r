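#' Subjects-by-features table with metadata
#'
#' A `feature_table` is a plain `data.frame` carrying one row per subject:
#' metadata columns (at least `subject_id` and `dataset`; optionally
#' `class` with levels HC/PD, `age` in years, `chps` in characters per
#' second, `lrd` in seconds, `group`) plus named numeric feature columns.
#' The set of feature columns is recorded in the `"features"` attribute so
#' metadata and features never get mixed up downstream.
#'
#' @param meta A data.frame of metadata columns including `subject_id`.
#' @param x Numeric matrix of feature values, one row per subject.
#' @param feature_names Optional column names for `x`.
#' @param dataset Dataset label recycled into a `dataset` column when not
#'   already present in `meta`.
#' @return A `data.frame` of class `feature_table`.
#' @export
feature_table <- function(meta, x, feature_names = colnames(x), dataset = NULL) {
  x <- as.matrix(x)
  if (nrow(meta) != nrow(x)) stop2("metadata and feature matrix row counts differ")
  if (is.null(feature_names)) {
    feature_names <- sprintf("f%03d", seq_len(ncol(x)))
  }
  if (anyDuplicated(feature_names)) stop2("feature names must be unique")
  if (any(!is.finite(x))) stop2("feature values must be finite (no missing values)")
  if (!"subject_id" %in% names(meta)) stop2("metadata must contain subject_id")
  if (!is.null(dataset) && !"dataset" %in% names(meta)) meta$dataset <- dataset
  colnames(x) <- feature_names
  out <- cbind(meta, as.data.frame(x, optional = TRUE))
  class(out) <- c("feature_table", "data.frame")
  attr(out, "features") <- feature_names
  out
}

#' @rdname feature_table
#' @param tbl A `feature_table`.
#' @return `feature_names()` returns the feature column names;
#'   `feature_matrix()` the numeric feature matrix.
#' @export
feature_names <- function(tbl) {
  f <- attr(tbl, "features")
  if (is.null(f)) stop2("not a feature_table: missing 'features' attribute")
  f
}

#' @rdname feature_table
#' @export
feature_matrix <- function(tbl) {
  as.matrix(tbl[, feature_names(tbl), drop = FALSE])
}

# Replace the feature block, keeping metadata columns.
set_features <- function(tbl, x, feature_names) {
  meta <- tbl[, setdiff(names(tbl), feature_names(tbl)), drop = FALSE]
  feature_table(meta, x, feature_names)
}

#' Write / read a feature table as tab-delimited text
#'
#' Plain text with a header row; the feature columns are re-identified on
#' read as every column after the known metadata columns.
#'
#' @param tbl A [feature_table()].
#' @param path File path.
#' @return `read_feature_table()` returns a `feature_table`.
#' @export
write_feature_table <- function(tbl, path) {
  utils::write.table(tbl, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  meta_cols <- intersect(
    c("subject_id", "dataset", "class", "group", "age", "chps", "lrd",
      "in_classification"),
    names(df)
  )
  feats <- setdiff(names(df), meta_cols)
  feature_table(df[, meta_cols, drop = FALSE],
                as.matrix(df[, feats, drop = FALSE]), feats)
}
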