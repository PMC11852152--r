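# JSONL interchange with annotation platforms. The primary dialect is the
# Doccano export: one object per line with a "text" field and a "label" list
# of [start, end, tag] triples; an alternate "entities" key (objects with
# start_offset/end_offset/label) is read-compatible.

#' Convert between annotated documents and JSONL annotation records
#'
#' `to_jsonl_record()` maps a [ner_document] to a list ready for JSON
#' serialization (`id`, `text`, `label` triples); `from_jsonl_record()`
#' inverts it, so `from_jsonl_record(to_jsonl_record(doc))` is the identity.
#'
#' @param doc A [ner_document].
#' @param record A named list parsed from one JSONL line.
#' @param doc_id Fallback identifier when the record carries none.
#' @return A list (record) or a [ner_document].
#' @export
to_jsonl_record <- function(doc) {
  validate_document(doc)
  list(id = doc$doc_id,
       text = doc$text,
       label = unname(lapply(seq_len(nrow(doc$spans)), function(i) {
         list(doc$spans$start[i], doc$spans$end[i], doc$spans$label[i])
       })))
}

#' @rdname to_jsonl_record
#' @export
from_jsonl_record <- function(record, doc_id = NULL) {
  if (is.null(record$text)) {
    nerval_stop("JSONL record has no 'text' field", class = "nerval_jsonl_error")
  }
  id <- as.character(record$id %||% doc_id %||% "doc")
  text <- utf8(record$text)
  raw <- record$label %||% record$entities %||% list()
  if (is.data.frame(raw)) raw <- split(raw, seq_len(nrow(raw)))
  triples <- lapply(raw, function(lab) {
    if (!is.null(names(lab)) && !is.null(lab$start_offset)) {
      list(start = lab$start_offset, end = lab$end_offset, label = lab$label)
    } else {
      lab <- unlist(lab, use.names = FALSE)
      list(start = lab[1], end = lab[2], label = lab[3])
    }
  })
  len <- n_chars(text)
  for (tr in triples) {
    s <- suppressWarnings(as.integer(tr$start))
    e <- suppressWarnings(as.integer(tr$end))
    if (is.na(s) || is.na(e) || s < 0L || e > len || s >= e) {
      nerval_stop(sprintf(
        "document %s: span triple [%s, %s, %s] out of bounds for text of length %d",
        id, tr$start, tr$end, tr$label, len),
        class = "nerval_jsonl_error")
    }
  }
  spans <- data.frame(
    start = vapply(triples, function(t) as.integer(t$start), integer(1)),
    end = vapply(triples, function(t) as.integer(t$end), integer(1)),
    label = vapply(triples, function(t) as.character(t$label), character(1)),
    stringsAsFactors = FALSE)
  ner_document(text, spans, doc_id = id)
}

#' Read and write Doccano-style JSONL corpora
#'
#' One annotated document per line. Writing then reading reproduces every
#' document exactly.
#'
#' @param docs List of [ner_document]s.
#' @param path File path.
#' @return `read_jsonl()` a list of [ner_document]s; `write_jsonl()` `path`,
#'   invisibly.
#' @export
write_jsonl <- function(docs, path) {
  lines <- vapply(docs, function(d) {
    jsonlite::toJSON(to_jsonl_record(d), auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_jsonl
#' @export
read_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(seq_along(lines), function(i) {
    rec <- jsonlite::fromJSON(lines[i], simplifyVector = FALSE)
    from_jsonl_record(rec, doc_id = sprintf("doc%03d", i))
  })
}
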