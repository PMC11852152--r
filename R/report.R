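# Score-report display and serialization. Displayed values are rounded
# half-up to two decimals; everything kept in the object (and written to
# JSON) stays at full precision.

fmt2 <- function(x) formatC(round_half_up(x, 2L), format = "f", digits = 2)

#' @export
print.ner_score_report <- function(x, ...) {
  cat(format(x), sep = "\n")
  invisible(x)
}

#' @export
format.ner_score_report <- function(x, ...) {
  pl <- x$per_label
  row <- function(name, p, r, f1, support) {
    sprintf("%-13s %9s %9s %9s %9s", name, p, r, f1, support)
  }
  c(sprintf("%s-match score report (%d evaluation units)",
            tools::toTitleCase(x$regime), x$n_units),
    "", row("", "precision", "recall", "f1-score", "support"),
    row(pl$label, fmt2(pl$precision), fmt2(pl$recall), fmt2(pl$f1),
        pl$support),
    "", row("accuracy", "", "", fmt2(x$accuracy), x$n_units),
    row("macro avg", fmt2(x$macro["precision"]), fmt2(x$macro["recall"]),
        fmt2(x$macro["f1"]), sum(pl$support)),
    row("weighted avg", fmt2(x$weighted["precision"]),
        fmt2(x$weighted["recall"]), fmt2(x$weighted["f1"]), sum(pl$support)))
}

#' Serialize a score report (and optional confusion matrix) to files
#'
#' Writes a machine-readable JSON file and, optionally, a plain-text table
#' and a confusion-matrix CSV next to it.
#'
#' @param report A `ner_score_report`.
#' @param path_json Output JSON path.
#' @param path_txt Optional plain-text table path.
#' @param confusion Optional `ner_confusion` to embed/write.
#' @param path_confusion Optional CSV path for the confusion counts.
#' @return `path_json`, invisibly.
#' @export
write_score_report <- function(report, path_json, path_txt = NULL,
                               confusion = NULL, path_confusion = NULL) {
  payload <- list(
    regime = report$regime,
    include_O = report$include_O,
    n_units = report$n_units,
    accuracy = report$accuracy,
    per_label = report$per_label,
    macro_avg = as.list(report$macro),
    weighted_avg = as.list(report$weighted))
  if (!is.null(confusion)) {
    payload$confusion <- list(labels = confusion$labels,
                              counts = confusion$counts,
                              class_counts = confusion$class_counts)
  }
  jsonlite::write_json(payload, path_json, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  if (!is.null(path_txt)) {
    writeLines(format(report), path_txt, useBytes = TRUE)
  }
  if (!is.null(confusion) && !is.null(path_confusion)) {
    utils::write.csv(as.data.frame(confusion$counts),
                     path_confusion, row.names = TRUE)
  }
  invisible(path_json)
}
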