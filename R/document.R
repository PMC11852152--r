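#' Entity labels of the mammography annotation schema
#'
#' The closed, case-sensitive set of entity classes: anatomy (`ANAT`),
#' impression (`IMP`), observation present (`OBS-P`), observation absent
#' (`OBS-A`) and observation uncertain (`OBS-U`). The non-entity sentinel
#' `"O"` marks unannotated text; it is a valid value in label-pair tables and
#' BIO tags but never appears as the label of a span.
#'
#' @return Character vector of the five entity labels.
#' @export
#' @examples
#' ner_labels()
ner_labels <- function() c("ANAT", "IMP", "OBS-P", "OBS-A", "OBS-U")

#' @rdname ner_labels
#' @export
o_label <- function() "O"

is_entity_label <- function(x) x %in% ner_labels()

check_labels <- function(labels, allow_o = FALSE, context = "span") {
  ok <- ner_labels()
  if (allow_o) ok <- c(ok, o_label())
  bad <- setdiff(unique(labels), ok)
  if (length(bad) > 0L) {
    nerval_stop(
      sprintf("unknown %s label(s): %s", context,
              paste(sQuote(bad), collapse = ", ")),
      class = "nerval_label_error")
  }
  invisible(labels)
}

#' Construct an annotated document
#'
#' An annotated document couples a report text with a set of labeled
#' character spans. Offsets are 0-based, half-open (`start` inclusive, `end`
#' exclusive) and counted in Unicode code points. Spans must lie within the
#' text, be sorted by start, and neither overlap nor nest; every span's
#' `surface` is the corresponding slice of `text`.
#'
#' @param text Report text (UTF-8).
#' @param spans A data frame with columns `start`, `end`, `label` (and
#'   optionally `surface`, recomputed from `text` when absent), or `NULL` for
#'   an unannotated document. Rows may be given in any order; they are sorted
#'   by `start`.
#' @param doc_id Opaque document identifier.
#' @return An object of class `ner_document`: a list with elements `doc_id`,
#'   `text` and `spans` (data frame `start`, `end`, `label`, `surface`).
#' @export
#' @examples
#' ner_document("right breast", data.frame(start = 0, end = 12, label = "ANAT"))
ner_document <- function(text, spans = NULL, doc_id = "doc") {
  text <- utf8(text)
  if (is.null(spans) || NROW(spans) == 0L) {
    spans <- data.frame(start = integer(), end = integer(),
                        label = character(), surface = character(),
                        stringsAsFactors = FALSE)
  } else {
    spans <- as.data.frame(spans, stringsAsFactors = FALSE)
    spans$start <- as.integer(spans$start)
    spans$end <- as.integer(spans$end)
    spans$label <- as.character(spans$label)
    spans <- spans[order(spans$start, spans$end), , drop = FALSE]
    spans$surface <- substr_cp(text, spans$start, spans$end)
    rownames(spans) <- NULL
    spans <- spans[, c("start", "end", "label", "surface")]
  }
  doc <- structure(list(doc_id = as.character(doc_id), text = text,
                        spans = spans),
                   class = "ner_document")
  validate_document(doc)
  doc
}

#' Validate an annotated document's invariants
#'
#' Checks offset bounds, ordering, the no-overlap/no-nesting rule, label
#' membership and surface/text agreement, raising a classed error on the
#' first violation.
#'
#' @param doc A [ner_document].
#' @return `doc`, invisibly.
#' @export
validate_document <- function(doc) {
  stopifnot(inherits(doc, "ner_document"))
  sp <- doc$spans
  if (nrow(sp) == 0L) return(invisible(doc))
  check_labels(sp$label)
  len <- n_chars(doc$text)
  if (any(sp$start < 0L) || any(sp$end > len) || any(sp$start >= sp$end)) {
    nerval_stop(sprintf("document %s: span offsets out of bounds (text length %d)",
                        doc$doc_id, len),
                class = "nerval_span_error")
  }
  if (is.unsorted(sp$start)) {
    nerval_stop(sprintf("document %s: spans not sorted by start", doc$doc_id),
                class = "nerval_span_error")
  }
  if (nrow(sp) > 1L && any(sp$start[-1L] < sp$end[-nrow(sp)])) {
    nerval_stop(sprintf("document %s: overlapping or nested spans", doc$doc_id),
                class = "nerval_span_error")
  }
  got <- substr_cp(doc$text, sp$start, sp$end)
  if (!identical(got, sp$surface)) {
    nerval_stop(sprintf("document %s: span surface does not match text slice",
                        doc$doc_id),
                class = "nerval_span_error")
  }
  invisible(doc)
}

#' @export
print.ner_document <- function(x, ...) {
  cat(sprintf("<ner_document %s: %d chars, %d spans>\n",
              x$doc_id, n_chars(x$text), nrow(x$spans)))
  if (nrow(x$spans) > 0L) print(x$spans)
  invisible(x)
}

#' @export
format.ner_document <- function(x, ...) {
  sprintf("<ner_document %s: %d chars, %d spans>",
          x$doc_id, n_chars(x$text), nrow(x$spans))
}
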