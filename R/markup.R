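# Inline HTML-span markup codec.
#
# The markup dialect is deliberately tiny: a flat sequence of text and
# `<span class="LABEL">...</span>` elements, one class attribute holding one
# entity label, no nesting, no other tags. A dedicated scanner (rather than a
# general HTML parser) is used so that structural errors carry exact
# character positions, stripped-text offsets are exact in code points, and
# unclosed/nested tags are rejected instead of being silently repaired.

TAG_RE <- "<span\\b[^>]*>|</span>"

#' Parse inline HTML-span entity markup
#'
#' Strips `<span class="LABEL">...</span>` tags from a markup fragment and
#' returns the plain text together with the character spans the tags
#' enclosed. Both the spaced (`class = "ANAT"`) and unspaced
#' (`class="ANAT"`) attribute dialects are accepted, and typographic quotes
#' around the attribute value are normalized before parsing.
#'
#' @param html_text Markup fragment (UTF-8 character scalar).
#' @param doc_id Identifier attached to the resulting document.
#' @param allow_unknown If `TRUE`, spans whose class is not one of
#'   [ner_labels()] are dropped with a warning instead of raising an error.
#' @return A [ner_document] whose `text` is the input with all tags removed
#'   and whose span offsets index that stripped text.
#' @export
#' @examples
#' doc <- parse_markup('<span class = "ANAT">right breast</span>')
#' doc$spans
parse_markup <- function(html_text, doc_id = "doc", allow_unknown = FALSE) {
  stopifnot(length(html_text) == 1L)
  html <- normalize_quotes(html_text)
  ml <- gregexpr(TAG_RE, html, perl = TRUE)
  m <- ml[[1]]
  if (m[1] == -1L) {
    return(ner_document(html, NULL, doc_id = doc_id))
  }
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  tags <- regmatches(html, ml)[[1]]

  text_parts <- character(0)
  out_len <- 0L          # code points emitted so far
  cursor <- 1L           # 1-based position in input
  open_at <- NA_integer_ # input position of the currently open tag
  open_label <- NA_character_
  open_out <- NA_integer_
  sp_start <- integer(0); sp_end <- integer(0); sp_label <- character(0)

  for (i in seq_along(tags)) {
    pre <- substr(html, cursor, starts[i] - 1L)
    text_parts <- c(text_parts, pre)
    out_len <- out_len + n_chars(pre)
    tag <- tags[i]
    if (startsWith(tag, "</")) {
      if (is.na(open_at)) {
        nerval_stop(sprintf(
          "unmatched </span> at character %d", starts[i]),
          class = "nerval_markup_error")
      }
      sp_start <- c(sp_start, open_out)
      sp_end <- c(sp_end, out_len)
      sp_label <- c(sp_label, open_label)
      open_at <- NA_integer_
    } else {
      if (!is.na(open_at)) {
        nerval_stop(sprintf(
          "nested <span> at character %d (previous span opened at %d not closed)",
          starts[i], open_at),
          class = "nerval_markup_error")
      }
      cls <- regmatches(tag, regexec('class\\s*=\\s*"([^"]*)"', tag))[[1]]
      if (length(cls) < 2L) {
        nerval_stop(sprintf(
          "span tag at character %d has no class attribute", starts[i]),
          class = "nerval_markup_error")
      }
      open_at <- starts[i]
      open_label <- cls[2]
      open_out <- out_len
    }
    cursor <- starts[i] + lens[i]
  }
  if (!is.na(open_at)) {
    nerval_stop(sprintf("unclosed <span> opened at character %d", open_at),
                class = "nerval_markup_error")
  }
  tail <- substr(html, cursor, nchar(html))
  text_parts <- c(text_parts, tail)
  text <- paste(text_parts, collapse = "")

  keep <- rep(TRUE, length(sp_label))
  unknown <- !is_entity_label(sp_label)
  if (any(unknown)) {
    if (allow_unknown) {
      nerval_warn(sprintf("dropping %d span(s) with unknown label(s): %s",
                          sum(unknown),
                          paste(sQuote(unique(sp_label[unknown])), collapse = ", ")),
                  class = "nerval_label_warning")
      keep <- !unknown
    } else {
      check_labels(sp_label, context = "span class")
    }
  }
  spans <- data.frame(start = sp_start[keep], end = sp_end[keep],
                      label = sp_label[keep], stringsAsFactors = FALSE)
  ner_document(text, spans, doc_id = doc_id)
}

#' Render an annotated document as inline HTML-span markup
#'
#' The inverse of [parse_markup()]: each span is wrapped in a canonical
#' unspaced `<span class="LABEL">...</span>` tag, so that
#' `parse_markup(render_markup(doc))` reproduces `doc` exactly.
#'
#' @param doc A valid [ner_document].
#' @return A markup string.
#' @export
render_markup <- function(doc) {
  validate_document(doc)
  sp <- doc$spans
  if (nrow(sp) == 0L) return(doc$text)
  parts <- character(0)
  cursor <- 0L
  for (i in seq_len(nrow(sp))) {
    parts <- c(parts,
               substr_cp(doc$text, cursor, sp$start[i]),
               sprintf('<span class="%s">%s</span>', sp$label[i], sp$surface[i]))
    cursor <- sp$end[i]
  }
  parts <- c(parts, substr_cp(doc$text, cursor, n_chars(doc$text)))
  paste(parts, collapse = "")
}

#' Extract the fenced code block from a model response
#'
#' Annotation prompts instruct the model to return its markup inside a fenced
#' code block; this pulls out the interior of the first triple-backtick fence
#' (with or without a language word). A response with no fence is returned
#' whole with a warning, and additional fences beyond the first are ignored
#' with a warning.
#'
#' @param llm_response Response text.
#' @return The markup payload.
#' @export
extract_code_block <- function(llm_response) {
  stopifnot(length(llm_response) == 1L)
  x <- utf8(llm_response)
  ml <- gregexpr("(?s)```[^\n`]*\n?(.*?)```", x, perl = TRUE)
  m <- ml[[1]]
  if (m[1] == -1L) {
    nerval_warn("response contains no fenced code block; returning it unchanged",
                class = "nerval_fence_warning")
    return(x)
  }
  if (length(m) > 1L) {
    nerval_warn(sprintf("response contains %d fenced blocks; using the first",
                        length(m)),
                class = "nerval_fence_warning")
  }
  block <- regmatches(x, ml)[[1]][1]
  inner <- sub("(?s)^```[^\n`]*\n?", "", block, perl = TRUE)
  inner <- sub("```$", "", inner)
  sub("\n$", "", inner)
}

BUNDLE_DELIM_RE <- "<!--\\s*doc:\\s*([^>]*?)\\s*-->"

#' Read and write multi-document markup bundles
#'
#' Several report fragments can be stored in one file, each introduced by an
#' HTML comment carrying its identifier (`<!-- doc: ID -->`). `write_markup_bundle()`
#' concatenates rendered documents under such delimiters and
#' `read_markup_bundle()` splits and parses them back.
#'
#' @param docs List of [ner_document] objects.
#' @param path File path; for reading, a path or a character scalar of
#'   bundle text.
#' @param ... Passed on to [parse_markup()].
#' @return `read_markup_bundle()` returns a list of [ner_document]s;
#'   `write_markup_bundle()` returns `path` invisibly.
#' @export
write_markup_bundle <- function(docs, path) {
  chunks <- vapply(docs, function(d) {
    sprintf("<!-- doc: %s -->\n%s", d$doc_id, render_markup(d))
  }, character(1))
  writeLines(chunks, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_markup_bundle
#' @export
read_markup_bundle <- function(path, ...) {
  txt <- if (file.exists(path)) {
    paste(readLines(path, encoding = "UTF-8", warn = FALSE), collapse = "\n")
  } else utf8(path)
  ml <- gregexpr(BUNDLE_DELIM_RE, txt, perl = TRUE)
  m <- ml[[1]]
  if (m[1] == -1L) {
    return(list(parse_markup(txt, ...)))
  }
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  heads <- regmatches(txt, ml)[[1]]
  ids <- sub(BUNDLE_DELIM_RE, "\\1", heads, perl = TRUE)
  bounds <- c(starts, nchar(txt) + 1L)
  lapply(seq_along(ids), function(i) {
    body <- substr(txt, starts[i] + lens[i], bounds[i + 1L] - 1L)
    body <- sub("^\n", "", body)
    body <- sub("\n+$", "", body)
    parse_markup(body, doc_id = ids[i], ...)
  })
}
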