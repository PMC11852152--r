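# Relaxed-match alignment: pair each predicted span with at most one
# reference span sharing at least `overlap_rule` characters, maximizing the
# total overlapped length. Spans within a document are disjoint intervals, so
# the bipartite overlap graph decomposes into small connected components
# (chains of consecutive straddling spans); each component is solved exactly
# by depth-first search. Among matchings of equal total overlap the one whose
# predicted-index assignment (in reference order) is lexicographically
# smallest is chosen, which keeps the procedure deterministic and symmetric
# under swapping the two documents.

#' Alignment configuration for relaxed matching
#'
#' @param overlap_rule Minimum number of shared characters for two spans to
#'   be pairable (>= 1).
#' @param o_unit Granularity at which text unannotated in both documents
#'   contributes agreeing `(O, O)` rows: `"token"` (one row per token,
#'   default) or `"run"` (one row per contiguous unannotated stretch).
#' @param tie_break Deterministic tie-break identifier; only
#'   `"lex"` (lexicographically smallest assignment) is implemented.
#' @return A `match_config` list.
#' @export
match_config <- function(overlap_rule = 1L, o_unit = c("token", "run"),
                         tie_break = "lex") {
  o_unit <- match.arg(o_unit)
  overlap_rule <- as.integer(overlap_rule)
  if (overlap_rule < 1L) {
    nerval_stop("overlap_rule must be >= 1", class = "nerval_config_error")
  }
  if (!identical(tie_break, "lex")) {
    nerval_stop("unknown tie_break rule", class = "nerval_config_error")
  }
  structure(list(overlap_rule = overlap_rule, o_unit = o_unit,
                 tie_break = tie_break),
            class = "match_config")
}

span_overlap <- function(s1, e1, s2, e2) pmax(0L, pmin(e1, e2) - pmax(s1, s2))

# Exact maximum-total-overlap one-to-one matching.
# w: n_ref x n_pred matrix of overlaps (0 = no edge).
# Returns integer vector: for each reference span the matched predicted
# index, or NA.
max_overlap_matching <- function(w) {
  n <- nrow(w); m <- ncol(w)
  assign <- rep(NA_integer_, n)
  if (n == 0L || m == 0L || all(w == 0)) return(assign)
  # connected components over the bipartite overlap graph
  comp_ref <- rep(0L, n); comp_pred <- rep(0L, m); ncomp <- 0L
  for (i in seq_len(n)) {
    if (comp_ref[i] != 0L || all(w[i, ] == 0)) next
    ncomp <- ncomp + 1L
    queue_r <- i
    while (length(queue_r) > 0L) {
      r <- queue_r[1]; queue_r <- queue_r[-1]
      if (comp_ref[r] != 0L) next
      comp_ref[r] <- ncomp
      for (p in which(w[r, ] > 0)) {
        if (comp_pred[p] == 0L) {
          comp_pred[p] <- ncomp
          queue_r <- c(queue_r, which(w[, p] > 0))
        }
      }
    }
  }
  for (k in seq_len(ncomp)) {
    refs <- which(comp_ref == k)
    preds <- which(comp_pred == k)
    sub <- w[refs, preds, drop = FALSE]
    best <- solve_component(sub)
    assign[refs] <- ifelse(is.na(best), NA_integer_, preds[best])
  }
  assign
}

# DFS over reference spans of one component; returns assignment of local
# predicted indices (or NA), maximizing total weight with lexicographic
# tie-break on the assignment vector (smaller index preferred, NA last).
solve_component <- function(w) {
  n <- nrow(w); m <- ncol(w)
  best_total <- -1L
  best_assign <- rep(NA_integer_, n)
  cur <- rep(NA_integer_, n)
  used <- rep(FALSE, m)
  lex_smaller <- function(a, b) {
    # is a lexicographically smaller than b (NA treated as +Inf)?
    av <- ifelse(is.na(a), Inf, a); bv <- ifelse(is.na(b), Inf, b)
    d <- which(av != bv)
    length(d) > 0L && av[d[1]] < bv[d[1]]
  }
  recurse <- function(i, total) {
    if (i > n) {
      if (total > best_total ||
          (total == best_total && lex_smaller(cur, best_assign))) {
        best_total <<- total
        best_assign <<- cur
      }
      return(invisible())
    }
    for (p in which(w[i, ] > 0 & !used)) {
      used[p] <<- TRUE; cur[i] <<- p
      recurse(i + 1L, total + w[i, p])
      used[p] <<- FALSE; cur[i] <<- NA_integer_
    }
    recurse(i + 1L, total)
  }
  recurse(1L, 0L)
  best_assign
}

#' Align reference and predicted annotations into label pairs
#'
#' Produces the relaxed-match evaluation table for one document pair: each
#' matched span pair yields a `(true label, predicted label)` row, unmatched
#' reference spans yield `(label, O)`, unmatched predicted spans `(O,
#' label)`, and text unannotated in both documents contributes `(O, O)` rows
#' at the configured granularity. Matching is one-to-one, requires at least
#' `overlap_rule` shared characters, and maximizes total character overlap.
#'
#' @param reference,predicted [ner_document]s over the identical text.
#' @param config A [match_config()].
#' @return A [label_pairs()] data frame in document order.
#' @export
#' @examples
#' ref <- ner_document("right breast unremarkable",
#'                     data.frame(start = 0, end = 12, label = "ANAT"))
#' pred <- ner_document("right breast unremarkable",
#'                      data.frame(start = 6, end = 12, label = "ANAT"))
#' align_entities(ref, pred)
align_entities <- function(reference, predicted, config = match_config()) {
  validate_document(reference)
  validate_document(predicted)
  if (!identical(reference$text, predicted$text)) {
    nerval_stop(sprintf(
      "documents %s / %s have different texts; alignment requires a shared text",
      reference$doc_id, predicted$doc_id),
      class = "nerval_alignment_error")
  }
  rs <- reference$spans; ps <- predicted$spans
  w <- matrix(0L, nrow(rs), nrow(ps))
  if (nrow(rs) > 0L && nrow(ps) > 0L) {
    for (i in seq_len(nrow(rs))) {
      w[i, ] <- span_overlap(rs$start[i], rs$end[i], ps$start, ps$end)
    }
    w[w < config$overlap_rule] <- 0L
  }
  assign <- max_overlap_matching(w)

  pos <- integer(0); y_true <- character(0); y_pred <- character(0)
  surface <- character(0)
  for (i in seq_len(nrow(rs))) {
    pos <- c(pos, rs$start[i])
    surface <- c(surface, rs$surface[i])
    y_true <- c(y_true, rs$label[i])
    y_pred <- c(y_pred,
                if (is.na(assign[i])) o_label() else ps$label[assign[i]])
  }
  unmatched_pred <- setdiff(seq_len(nrow(ps)), assign[!is.na(assign)])
  for (j in unmatched_pred) {
    pos <- c(pos, ps$start[j])
    surface <- c(surface, ps$surface[j])
    y_true <- c(y_true, o_label())
    y_pred <- c(y_pred, ps$label[j])
  }

  # O units: tokens untouched by any span in either document
  tok <- tokenize(reference$text)
  if (nrow(tok) > 0L) {
    covered <- rep(FALSE, nrow(tok))
    all_sp <- rbind(rs[, c("start", "end")], ps[, c("start", "end")])
    for (k in seq_len(nrow(all_sp))) {
      covered <- covered |
        (tok$start < all_sp$end[k] & tok$end > all_sp$start[k])
    }
    free <- which(!covered)
    if (length(free) > 0L) {
      if (config$o_unit == "token") {
        pos <- c(pos, tok$start[free])
        surface <- c(surface, tok$surface[free])
        y_true <- c(y_true, rep(o_label(), length(free)))
        y_pred <- c(y_pred, rep(o_label(), length(free)))
      } else {
        run_id <- cumsum(c(1L, diff(free) != 1L))
        for (g in split(free, run_id)) {
          pos <- c(pos, tok$start[g[1]])
          surface <- c(surface,
                       substr_cp(reference$text, tok$start[g[1]],
                                 tok$end[g[length(g)]]))
          y_true <- c(y_true, o_label())
          y_pred <- c(y_pred, o_label())
        }
      }
    }
  }
  ord <- order(pos)
  out <- data.frame(doc_id = reference$doc_id,
                    surface = surface[ord],
                    y_true = y_true[ord],
                    y_pred = y_pred[ord],
                    stringsAsFactors = FALSE)
  out$Compare <- out$y_true == out$y_pred
  label_pairs(out)
}

#' Align whole corpora of reference and predicted documents
#'
#' Documents are matched by `doc_id`; each pair is aligned with
#' [align_entities()] and the tables are concatenated.
#'
#' @param reference,predicted Lists of [ner_document]s with matching ids.
#' @param config A [match_config()].
#' @return A [label_pairs()] data frame.
#' @export
align_corpus <- function(reference, predicted, config = match_config()) {
  ids_r <- vapply(reference, function(d) d$doc_id, character(1))
  ids_p <- vapply(predicted, function(d) d$doc_id, character(1))
  if (!setequal(ids_r, ids_p)) {
    nerval_stop("reference and predicted corpora have different doc_ids",
                class = "nerval_alignment_error")
  }
  tabs <- lapply(ids_r, function(id) {
    align_entities(reference[[which(ids_r == id)[1]]],
                   predicted[[which(ids_p == id)[1]]],
                   config = config)
  })
  label_pairs(do.call(rbind, tabs))
}
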