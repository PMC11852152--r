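# Whitespace + punctuation tokenizer. Language-agnostic by design: tokens are
# maximal non-whitespace runs with leading/trailing Unicode punctuation peeled
# off as standalone tokens, which is what downstream BIO emission and O-unit
# counting need. Interior punctuation (hyphenated compounds) stays attached.

PUNCT_RE <- "\\p{P}|\\p{S}"

#' Tokenize text into offset-carrying tokens
#'
#' Splits on whitespace, then detaches leading and trailing punctuation
#' characters of each run as standalone tokens. Offsets are 0-based half-open
#' code-point positions into the input, so concatenating surfaces with the
#' original gaps reconstructs the text.
#'
#' @param text Character scalar.
#' @return Data frame with columns `surface`, `start`, `end` (possibly
#'   zero rows).
#' @export
#' @examples
#' tokenize("atelectasis -infarction")$surface
tokenize <- function(text) {
  text <- utf8(text)
  empty <- data.frame(surface = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE)
  if (!nzchar(text)) return(empty)
  m <- gregexpr("\\S+", text, perl = TRUE)[[1]]
  if (m[1] == -1L) return(empty)
  run_start <- as.integer(m) - 1L
  run_len <- attr(m, "match.length")
  surfaces <- character(0); starts <- integer(0); ends <- integer(0)
  push <- function(s, e) {
    surfaces <<- c(surfaces, substr_cp(text, s, e))
    starts <<- c(starts, s); ends <<- c(ends, e)
  }
  for (i in seq_along(run_start)) {
    s <- run_start[i]; e <- run_start[i] + run_len[i]
    # peel leading punctuation
    while (s < e - 1L &&
           grepl(PUNCT_RE, substr_cp(text, s, s + 1L), perl = TRUE)) {
      push(s, s + 1L); s <- s + 1L
    }
    # peel trailing punctuation (collect, emit after the core)
    trail <- integer(0)
    while (e - 1L > s &&
           grepl(PUNCT_RE, substr_cp(text, e - 1L, e), perl = TRUE)) {
      trail <- c(e - 1L, trail); e <- e - 1L
    }
    push(s, e)
    for (t in trail) push(t, t + 1L)
  }
  data.frame(surface = surfaces, start = starts, end = ends,
             stringsAsFactors = FALSE)
}

#' Detach punctuation adjacent to entity boundaries
#'
#' Inserts a single space wherever a span boundary abuts a punctuation
#' character outside the span, remapping all span offsets so that every
#' surface is preserved. Required upstream of exact-match tokenized
#' evaluation where a mark glued to an entity (as in `"atelectasis
#' -infarction"`) would otherwise fuse with its first token.
#'
#' @param doc A [ner_document].
#' @return A [ner_document] over the whitespace-adjusted text.
#' @export
detach_punctuation <- function(doc) {
  validate_document(doc)
  sp <- doc$spans
  if (nrow(sp) == 0L) return(doc)
  txt <- doc$text
  len <- n_chars(txt)
  is_punct_at <- function(i) {
    i >= 0L && i < len &&
      grepl(PUNCT_RE, substr_cp(txt, i, i + 1L), perl = TRUE)
  }
  ins <- integer(0)
  for (k in seq_len(nrow(sp))) {
    if (is_punct_at(sp$start[k] - 1L)) ins <- c(ins, sp$start[k])
    if (is_punct_at(sp$end[k])) ins <- c(ins, sp$end[k])
  }
  ins <- sort(unique(ins))
  if (length(ins) == 0L) return(doc)
  pieces <- character(0); cursor <- 0L
  for (p in ins) {
    pieces <- c(pieces, substr_cp(txt, cursor, p), " ")
    cursor <- p
  }
  pieces <- c(pieces, substr_cp(txt, cursor, len))
  new_text <- paste(pieces, collapse = "")
  new_start <- sp$start + vapply(sp$start, function(s) sum(ins <= s), integer(1))
  new_end <- sp$end + vapply(sp$end, function(e) sum(ins < e), integer(1))
  ner_document(new_text,
               data.frame(start = new_start, end = new_end, label = sp$label,
                          stringsAsFactors = FALSE),
               doc_id = doc$doc_id)
}
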