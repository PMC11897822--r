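# Labelled feature container and delimited-text I/O.

#' Labelled feature matrix for binary discriminant analysis
#'
#' Bundles an N x M real feature matrix with binary class labels. Class 1 is
#' always the lexicographically/numerically smaller label, so the
#' between-class direction `mean(class 1) - mean(class 2)` is well defined
#' and deterministic across runs.
#'
#' @param matrix numeric N x M matrix; rows are samples, columns features.
#' @param labels length-N vector with exactly two distinct values.
#' @param feature_names optional character vector of length M.
#' @return an object of class `labelled_features` with elements `matrix`,
#'   `labels` (original values), `label_order` (class 1 first),
#'   `class_counts` (named `N1`, `N2`) and `feature_names`.
#' @examples
#' lf <- labelled_features(matrix(rnorm(20), 10, 2), rep(c("a", "b"), 5))
#' lf$class_counts
#' @export
labelled_features <- function(matrix, labels, feature_names = NULL) {
  matrix <- as.matrix(matrix)
  storage.mode(matrix) <- "double"
  if (nrow(matrix) != length(labels))
    stop_dimension("number of rows of `matrix` must equal length of `labels`")
  assert_finite(matrix, "feature matrix")
  if (anyNA(labels)) stop_validation("labels contain NA")
  lev <- sort(unique(as.character(labels)))
  if (length(lev) != 2L)
    stop_validation(sprintf("exactly 2 classes required, found %d", length(lev)))
  counts <- c(N1 = sum(as.character(labels) == lev[1]),
              N2 = sum(as.character(labels) == lev[2]))
  if (any(counts == 0L)) stop_validation("both classes must be non-empty")
  fn <- feature_names %||% colnames(matrix) %||%
    paste0("f", seq_len(ncol(matrix)))
  if (length(fn) != ncol(matrix))
    stop_dimension("feature_names length must equal ncol(matrix)")
  colnames(matrix) <- fn
  structure(
    list(matrix = matrix, labels = labels, label_order = lev,
         class_counts = counts, feature_names = fn),
    class = "labelled_features")
}

#' @export
print.labelled_features <- function(x, ...) {
  cat(sprintf("<labelled_features> %d samples x %d features; classes %s (N1=%d), %s (N2=%d)\n",
              nrow(x$matrix), ncol(x$matrix),
              x$label_order[1], x$class_counts[["N1"]],
              x$label_order[2], x$class_counts[["N2"]]))
  invisible(x)
}

# rows of class j (j = 1 means the smaller label)
class_rows <- function(lf, j) {
  which(as.character(lf$labels) == lf$label_order[j])
}

#' Read/write labelled features as delimited text
#'
#' Tab-separated with a header row of feature names plus one label column.
#'
#' @param path file path.
#' @param label_col name of the label column (default `"label"`).
#' @return `read_features()` returns a [labelled_features] object;
#'   `write_features()` returns `path` invisibly.
#' @export
read_features <- function(path, label_col = "label") {
  df <- utils::read.delim(path, check.names = FALSE)
  if (!label_col %in% names(df))
    stop_validation(sprintf("label column '%s' not found in %s", label_col, path))
  labels <- df[[label_col]]
  mat <- as.matrix(df[setdiff(names(df), label_col)])
  labelled_features(mat, labels)
}

#' @rdname read_features
#' @param lf a [labelled_features] object.
#' @export
write_features <- function(lf, path, label_col = "label") {
  stopifnot(inherits(lf, "labelled_features"))
  df <- as.data.frame(lf$matrix, check.names = FALSE)
  df[[label_col]] <- lf$labels
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
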