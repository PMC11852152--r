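# Controlled error injection for evaluator testing: an annotated document is
# degraded into a simulated "prediction" with known boundary-shift, label-
# swap, deletion and spurious-insertion rates, so that alignment and scoring
# can be checked for parameter recovery.

#' Perturbation configuration
#'
#' @param p_boundary_shift Per-span probability of shifting both boundaries
#'   (overlap with the original span is always preserved).
#' @param p_label_swap Per-span probability of swapping the label, uniformly
#'   over the other entity labels.
#' @param p_delete Per-span probability of dropping the span.
#' @param p_insert Per unannotated token, probability of inserting a spurious
#'   single-token span with a uniform random label.
#' @param max_shift Maximum boundary displacement in characters.
#' @param seed Optional integer seed; when `NULL` the current RNG stream is
#'   used.
#' @return A `perturb_config` list.
#' @export
perturb_config <- function(p_boundary_shift = 0, p_label_swap = 0,
                           p_delete = 0, p_insert = 0, max_shift = 3L,
                           seed = NULL) {
  probs <- c(p_boundary_shift, p_label_swap, p_delete, p_insert)
  if (any(probs < 0 | probs > 1)) {
    nerval_stop("perturbation probabilities must lie in [0, 1]",
                class = "nerval_config_error")
  }
  structure(list(p_boundary_shift = p_boundary_shift,
                 p_label_swap = p_label_swap,
                 p_delete = p_delete, p_insert = p_insert,
                 max_shift = as.integer(max_shift),
                 seed = seed),
            class = "perturb_config")
}

#' Inject controlled annotation errors into a document
#'
#' Spans are processed in order with a fixed number of random draws each
#' (delete, swap, shift decisions and their parameters), so a fixed seed
#' replays exactly. Deleted spans vanish; swapped spans keep their offsets
#' with a uniformly different entity label; shifted spans move each boundary
#' by up to `max_shift` characters, clamped so the span keeps at least one
#' character of overlap with its original extent, stays inside the text and
#' never collides with a neighboring span. Spurious single-token spans are
#' then inserted over tokens unannotated in both the original and the
#' perturbed document.
#'
#' @param doc A [ner_document].
#' @param config A [perturb_config()].
#' @return A perturbed [ner_document] over the same text.
#' @export
perturb <- function(doc, config = perturb_config()) {
  validate_document(doc)
  run <- function() perturb_impl(doc, config)
  if (!is.null(config$seed)) with_local_seed(config$seed, run()) else run()
}

perturb_impl <- function(doc, config) {
  sp <- doc$spans
  len <- n_chars(doc$text)
  labels <- ner_labels()
  n <- nrow(sp)
  keep <- logical(n); lab <- character(n)
  new_start <- integer(n); new_end <- integer(n)
  for (i in seq_len(n)) {
    u <- stats::runif(3)               # delete, swap, shift decisions
    swap_pick <- sample.int(length(labels) - 1L, 1L)
    shifts <- sample.int(2L * config$max_shift + 1L, 2L, replace = TRUE) -
      config$max_shift - 1L            # in [-max_shift, max_shift]
    keep[i] <- u[1] >= config$p_delete
    lab[i] <- sp$label[i]
    if (u[2] < config$p_label_swap) {
      lab[i] <- setdiff(labels, sp$label[i])[swap_pick]
    }
    s <- sp$start[i]; e <- sp$end[i]
    if (u[3] < config$p_boundary_shift) {
      prev_end <- if (i > 1L) sp$end[i - 1L] else 0L
      next_start <- if (i < n) sp$start[i + 1L] else len
      # each span may claim at most half of the gap to its neighbor
      ns <- s + shifts[1]
      ne <- e + shifts[2]
      ns <- max(ns, s - (s - prev_end) %/% 2L, 0L)
      ne <- min(ne, e + (next_start - e) %/% 2L, len)
      ns <- min(ns, e - 1L)            # preserve overlap with the original
      ne <- max(ne, s + 1L)
      if (ne <= ns) { ns <- s; ne <- e }
      s <- ns; e <- ne
    }
    new_start[i] <- s; new_end[i] <- e
  }
  out <- data.frame(start = new_start[keep], end = new_end[keep],
                    label = lab[keep], stringsAsFactors = FALSE)

  if (config$p_insert > 0) {
    tok <- tokenize(doc$text)
    if (nrow(tok) > 0L) {
      free <- rep(TRUE, nrow(tok))
      blockers <- rbind(sp[, c("start", "end")], out[, c("start", "end")])
      for (k in seq_len(nrow(blockers))) {
        free <- free & !(tok$start < blockers$end[k] &
                           tok$end > blockers$start[k])
      }
      cand <- which(free)
      u_ins <- stats::runif(length(cand))
      pick_lab <- sample(labels, length(cand), replace = TRUE)
      sel <- cand[u_ins < config$p_insert]
      if (length(sel) > 0L) {
        out <- rbind(out, data.frame(start = tok$start[sel],
                                     end = tok$end[sel],
                                     label = pick_lab[u_ins < config$p_insert],
                                     stringsAsFactors = FALSE))
      }
    }
  }
  ner_document(doc$text, out, doc_id = doc$doc_id)
}
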