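# BIO tag sequences. A corpus is represented as a list of sequences, each a
# list with character vectors `tokens` and `tags` of equal length; tags are
# "O" or "B-L"/"I-L" with L an entity label. The scheme is plain BIO
# (no BILOU/IOBES).

bio_sequence <- function(tokens, tags) {
  stopifnot(length(tokens) == length(tags))
  structure(list(tokens = as.character(tokens), tags = as.character(tags)),
            class = "bio_sequence")
}

#' Encode an annotated document as a BIO tag sequence
#'
#' Tokenizes the document text and assigns `B-label` to the first token of
#' each span, `I-label` to subsequent tokens, and `O` elsewhere. Every span
#' boundary must coincide with token boundaries; run [detach_punctuation()]
#' first when punctuation is glued to entities.
#'
#' @param doc A [ner_document].
#' @return A `bio_sequence`: list with `tokens`, `tags` and token offsets
#'   (`starts`, `ends`).
#' @export
doc_to_bio <- function(doc) {
  validate_document(doc)
  tok <- tokenize(doc$text)
  tags <- rep("O", nrow(tok))
  sp <- doc$spans
  for (k in seq_len(nrow(sp))) {
    inside <- tok$start >= sp$start[k] & tok$end <= sp$end[k]
    straddle <- tok$start < sp$end[k] & tok$end > sp$start[k] & !inside
    if (any(straddle)) {
      nerval_stop(sprintf(
        "document %s: span [%d,%d,%s] boundary splits token '%s' [%d,%d)",
        doc$doc_id, sp$start[k], sp$end[k], sp$label[k],
        tok$surface[which(straddle)[1]],
        tok$start[which(straddle)[1]], tok$end[which(straddle)[1]]),
        class = "nerval_alignment_error")
    }
    idx <- which(inside)
    if (length(idx) > 0L) {
      tags[idx] <- paste0("I-", sp$label[k])
      tags[idx[1]] <- paste0("B-", sp$label[k])
    }
  }
  out <- bio_sequence(tok$surface, tags)
  out$starts <- tok$start
  out$ends <- tok$end
  out
}

#' Decode a BIO sequence back into spans
#'
#' Inverse of [doc_to_bio()] for documents whose spans align with token
#' boundaries: contiguous `B-L`/`I-L` runs become spans over the original
#' character offsets.
#'
#' @param bio A `bio_sequence` carrying token offsets (as produced by
#'   [doc_to_bio()]).
#' @return Data frame of `start`, `end`, `label`.
#' @export
bio_to_spans <- function(bio) {
  stopifnot(!is.null(bio$starts), !is.null(bio$ends))
  ch <- bio_chunks(bio$tags)
  data.frame(start = bio$starts[ch$from],
             end = bio$ends[ch$to],
             label = ch$label,
             stringsAsFactors = FALSE)
}

# Extract entity chunks from a tag vector. Invalid transitions (I- with no
# matching B-) are repaired by promotion to B- when repair = TRUE (the
# lenient default of common chunk evaluators), otherwise they raise.
bio_chunks <- function(tags, repair = TRUE) {
  from <- integer(0); to <- integer(0); label <- character(0)
  cur_label <- NA_character_; cur_from <- NA_integer_
  flush <- function(i) {
    if (!is.na(cur_label)) {
      from <<- c(from, cur_from); to <<- c(to, i); label <<- c(label, cur_label)
    }
    cur_label <<- NA_character_
  }
  for (i in seq_along(tags)) {
    tag <- tags[i]
    if (tag == "O") {
      flush(i - 1L)
    } else if (startsWith(tag, "B-")) {
      flush(i - 1L)
      cur_label <- substring(tag, 3L)
      cur_from <- i
    } else if (startsWith(tag, "I-")) {
      lab <- substring(tag, 3L)
      if (is.na(cur_label) || cur_label != lab) {
        if (!repair) {
          nerval_stop(sprintf("invalid BIO transition to '%s' at position %d",
                              tag, i),
                      class = "nerval_bio_error")
        }
        nerval_warn(sprintf("repairing dangling '%s' at position %d to 'B-%s'",
                            tag, i, lab),
                    class = "nerval_bio_warning")
        flush(i - 1L)
        cur_label <- lab
        cur_from <- i
      }
    } else {
      nerval_stop(sprintf("malformed BIO tag '%s' at position %d", tag, i),
                  class = "nerval_bio_error")
    }
  }
  flush(length(tags))
  data.frame(from = from, to = to, label = label, stringsAsFactors = FALSE)
}

#' Expand a label-pair table into parallel BIO streams
#'
#' Each pair's surface is tokenized; its tokens receive `B-`/`I-` tags of
#' `y_true` in the true stream and of `y_pred` in the predicted stream (label
#' `O` maps to all-`O` tags). One BIO sequence is emitted per pair, so the
#' two streams are parallel and of equal length.
#'
#' @param pairs A label-pair data frame (see [label_pairs()]).
#' @return List with elements `true` and `pred`, each a list of
#'   `bio_sequence`s.
#' @export
pairs_to_bio <- function(pairs) {
  pairs <- label_pairs(pairs)
  tag_for <- function(label, n) {
    if (label == o_label()) rep("O", n)
    else c(paste0("B-", label), rep(paste0("I-", label), n - 1L))
  }
  true_seqs <- vector("list", nrow(pairs))
  pred_seqs <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    toks <- tokenize(pairs$surface[i])$surface
    if (length(toks) == 0L) {
      nerval_stop(sprintf("pair %d has an empty surface", i),
                  class = "nerval_pair_error")
    }
    true_seqs[[i]] <- bio_sequence(toks, tag_for(pairs$y_true[i], length(toks)))
    pred_seqs[[i]] <- bio_sequence(toks, tag_for(pairs$y_pred[i], length(toks)))
  }
  list(true = true_seqs, pred = pred_seqs)
}

#' Read and write two-column BIO files
#'
#' The on-disk format is one `token<TAB>tag` line per token with a blank line
#' between sequences.
#'
#' @param seqs List of `bio_sequence`s.
#' @param path File path.
#' @return `read_bio()` a list of `bio_sequence`s; `write_bio()` `path`,
#'   invisibly.
#' @export
write_bio <- function(seqs, path) {
  blocks <- vapply(seqs, function(s) {
    paste(paste(s$tokens, s$tags, sep = "\t"), collapse = "\n")
  }, character(1))
  writeLines(paste(blocks, collapse = "\n\n"), path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_bio
#' @export
read_bio <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  breaks <- cumsum(!nzchar(trimws(lines)))
  keep <- nzchar(trimws(lines))
  groups <- split(lines[keep], breaks[keep])
  unname(lapply(groups, function(g) {
    parts <- strsplit(g, "\t", fixed = TRUE)
    bio_sequence(vapply(parts, `[`, character(1), 1L),
                 vapply(parts, `[`, character(1), 2L))
  }))
}
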