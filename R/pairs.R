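# Label-pair tables: one evaluation row per entity instance (or O unit),
# with the reviewed true label and the model's predicted label. This is the
# relaxed-match evaluation currency; files use a configurable delimiter
# (";" by default) and may carry extra columns (e.g. "Compare") that are
# preserved on round trip but ignored by scoring.

#' Construct or validate a label-pair table
#'
#' @param x Data frame with at least `y_true` and `y_pred` columns (values in
#'   [ner_labels()] or `"O"`); `doc_id` and `surface` are filled with
#'   defaults when missing. Extra columns are kept.
#' @return A `label_pairs` data frame with `doc_id`, `surface`, `y_true`,
#'   `y_pred` first.
#' @export
#' @examples
#' label_pairs(data.frame(y_true = "ANAT", y_pred = "ANAT", surface = "axilla"))
label_pairs <- function(x) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  miss <- setdiff(c("y_true", "y_pred"), names(x))
  if (length(miss) > 0L) {
    nerval_stop(sprintf("pair table lacks required column(s): %s",
                        paste(miss, collapse = ", ")),
                class = "nerval_pair_error")
  }
  if (is.null(x$doc_id)) x$doc_id <- rep("doc", nrow(x))
  if (is.null(x$surface)) x$surface <- rep("", nrow(x))
  x$y_true <- as.character(x$y_true)
  x$y_pred <- as.character(x$y_pred)
  check_labels(c(x$y_true, x$y_pred), allow_o = TRUE, context = "pair")
  front <- c("doc_id", "surface", "y_true", "y_pred")
  x <- x[, c(front, setdiff(names(x), front)), drop = FALSE]
  class(x) <- c("label_pairs", "data.frame")
  x
}

#' Read and write delimited label-pair files
#'
#' Files must carry a header row with `y_true` and `y_pred` columns; the
#' field delimiter is configurable (the conventional export uses `";"`).
#' Row order and extra columns are preserved.
#'
#' @param path File path.
#' @param delimiter Single-character field separator.
#' @param pairs A `label_pairs` data frame.
#' @return `read_pairs()` a `label_pairs` data frame; `write_pairs()` `path`,
#'   invisibly.
#' @export
read_pairs <- function(path, delimiter = ";") {
  df <- utils::read.csv(path, sep = delimiter, check.names = FALSE,
                        colClasses = "character", fileEncoding = "UTF-8")
  if (!all(c("y_true", "y_pred") %in% names(df))) {
    nerval_stop(sprintf("file %s lacks y_true/y_pred columns", path),
                class = "nerval_pair_error")
  }
  label_pairs(df)
}

#' @rdname read_pairs
#' @export
write_pairs <- function(pairs, path, delimiter = ";") {
  pairs <- label_pairs(pairs)
  utils::write.table(pairs, path, sep = delimiter, row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
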