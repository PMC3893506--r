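#' Construct an expression matrix
#'
#' The common currency of the workflow: a features x time-points matrix of
#' log2 expression ratios relative to the time-0 control sample. Rows are
#' uniquely named features (genes or microRNAs), columns are ordered time
#' labels; the control column itself is not stored (its ratio is identically
#' zero) and is re-attached as an implicit baseline where a method needs it.
#'
#' @param values Numeric matrix (features x time points), all finite.
#' @param feature_ids Character vector of unique row ids (defaults to
#'   existing rownames).
#' @param time_labels Character vector of ordered column labels (defaults to
#'   existing colnames).
#' @return A numeric matrix with class \code{"expression_matrix"}.
#' @export
expression_matrix <- function(values, feature_ids = rownames(values),
                              time_labels = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(feature_ids) || is.null(time_labels))
    abort_input("expression matrix needs feature ids and time labels")
  if (anyDuplicated(feature_ids))
    abort_input("duplicate feature ids: ",
                paste(unique(feature_ids[duplicated(feature_ids)]), collapse = ", "))
  if (length(feature_ids) != nrow(values) || length(time_labels) != ncol(values))
    abort_input("dimension mismatch between values and labels")
  if (nrow(values) > 0L && ncol(values) > 0L && !all(is.finite(values)))
    abort_input("expression values must be finite")
  storage.mode(values) <- "double"
  dimnames(values) <- list(feature_ids, time_labels)
  class(values) <- c("expression_matrix", class(values))
  values
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d features x %d time points\n",
              nrow(x), ncol(x)))
  if (nrow(x)) print(utils::head(unclass(x), 5L))
  invisible(x)
}

#' Read / write an expression matrix as TSV
#'
#' The interchange format is a tab-separated table whose first column
#' (\code{feature_id}) holds row ids and whose remaining columns are the
#' ordered time labels.
#'
#' @param path File path.
#' @return \code{read_expression_matrix} returns an
#'   \code{\link{expression_matrix}}; the writer returns \code{path}
#'   invisibly.
#' @export
read_expression_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, colClasses = NA)
  if (!"feature_id" %in% names(df)[1])
    abort_input("first column of ", path, " must be 'feature_id'")
  vals <- as.matrix(df[, -1, drop = FALSE])
  expression_matrix(vals, feature_ids = as.character(df[[1]]),
                    time_labels = colnames(vals))
}

#' @rdname read_expression_matrix
#' @param x An \code{\link{expression_matrix}}.
#' @export
write_expression_matrix <- function(x, path) {
  df <- data.frame(feature_id = rownames(x), unclass(x),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# prepend the implicit time-0 baseline (log2 ratio 0) as first column
prepend_baseline <- function(x, label = "0h") {
  out <- cbind(0, unclass(x))
  colnames(out) <- c(label, colnames(x))
  rownames(out) <- rownames(x)
  out
}
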