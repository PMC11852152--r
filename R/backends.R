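# Offline annotation backends. The backend contract is a stateless,
# synchronous function `f(prompt, doc_id)` returning response text; live API
# adapters satisfy the same contract but are deliberately out of the test
# surface. Backends here exist for reproducible offline runs: replaying
# stored responses, echoing the target unannotated, and emitting controlled
# perturbations of known references.

fence <- function(markup) paste0("```\n", markup, "\n```")

#' Replay backend: stored fixture responses keyed by document id
#'
#' @param fixtures Either a directory containing `<doc_id>.txt` response
#'   files or a named list/character vector of responses.
#' @return A backend function.
#' @export
backend_replay <- function(fixtures) {
  if (is.character(fixtures) && length(fixtures) == 1L && dir.exists(fixtures)) {
    dir <- fixtures
    function(prompt, doc_id = NULL) {
      path <- file.path(dir, paste0(doc_id, ".txt"))
      if (is.null(doc_id) || !file.exists(path)) {
        nerval_stop(sprintf("no replay fixture for doc_id %s",
                            doc_id %||% "<missing>"),
                    class = "nerval_backend_error")
      }
      paste(readLines(path, encoding = "UTF-8", warn = FALSE), collapse = "\n")
    }
  } else {
    store <- as.list(fixtures)
    function(prompt, doc_id = NULL) {
      if (is.null(doc_id) || is.null(store[[doc_id]])) {
        nerval_stop(sprintf("no replay fixture for doc_id %s",
                            doc_id %||% "<missing>"),
                    class = "nerval_backend_error")
      }
      store[[doc_id]]
    }
  }
}

#' Identity backend: echoes the target report without annotations
#'
#' Extracts the text between the transitional phrase and the first control
#' phrase of the prompt and returns it, fenced, with zero spans. Useful as a
#' divergence-free baseline.
#'
#' @param transitional_phrase Phrase delimiting the target inside the prompt.
#' @return A backend function.
#' @export
backend_identity <- function(transitional_phrase = default_transitional_phrase()) {
  function(prompt, doc_id = NULL) {
    pos <- regexpr(transitional_phrase, prompt, fixed = TRUE)
    if (pos == -1L) {
      nerval_stop("prompt contains no transitional phrase; cannot locate target",
                  class = "nerval_backend_error")
    }
    rest <- substr(prompt, pos + attr(pos, "match.length"), nchar(prompt))
    ctrl <- regexpr("\n###", rest, fixed = TRUE)
    target <- if (ctrl == -1L) rest else substr(rest, 1L, ctrl - 1L)
    fence(trimws(target))
  }
}

#' Perturbing mock backend: known references with injected errors
#'
#' Looks up the reference document for `doc_id`, perturbs its annotations
#' under the configured error rates (see [perturb()]) and returns the
#' perturbed markup in a fenced block. Each document is perturbed under a
#' seed derived deterministically from the backend seed and the document's
#' position, so runs replay exactly.
#'
#' @param reference_docs List of [ner_document]s.
#' @param config A [perturb_config()].
#' @param seed Integer backend seed.
#' @return A backend function.
#' @export
backend_perturb <- function(reference_docs, config, seed = 1L) {
  ids <- vapply(reference_docs, function(d) d$doc_id, character(1))
  function(prompt, doc_id = NULL) {
    idx <- match(doc_id, ids)
    if (is.na(idx)) {
      nerval_stop(sprintf("no reference document for doc_id %s",
                          doc_id %||% "<missing>"),
                  class = "nerval_backend_error")
    }
    doc_cfg <- config
    doc_cfg$seed <- (as.integer(seed) + 7919L * idx) %% 2147483647L
    fence(render_markup(perturb(reference_docs[[idx]], doc_cfg)))
  }
}
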