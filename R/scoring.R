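# Relaxed (pair-based) and exact (span-boundary) scoring.
#
# All metrics reduce to per-class TP/FP/FN (plus TN in the pair-based,
# one-vs-rest setting): precision = TP/(TP+FP), recall = TP/(TP+FN), and
# F1 = 2PR/(P+R), with zero denominators mapping to 0 by the usual
# classification-report convention.

#' Precision, recall and F1 from raw counts
#'
#' @param tp,fp,fn Non-negative counts.
#' @param zero_division How to handle a zero denominator: `"zero"` returns 0
#'   silently, `"warn"` returns 0 with a warning, `"raise"` errors.
#' @return Named numeric vector `precision`, `recall`, `f1`.
#' @export
#' @examples
#' f1_from_counts(784, 11, 1)
f1_from_counts <- function(tp, fp, fn, zero_division = c("zero", "warn", "raise")) {
  zero_division <- match.arg(zero_division)
  if (any(c(tp, fp, fn) < 0)) {
    nerval_stop("negative counts", class = "nerval_count_error")
  }
  safe_div <- function(num, den, what) {
    if (den == 0) {
      if (zero_division == "raise") {
        nerval_stop(sprintf("zero denominator computing %s", what),
                    class = "nerval_count_error")
      }
      if (zero_division == "warn") {
        nerval_warn(sprintf("zero denominator computing %s; reporting 0", what),
                    class = "nerval_zero_division")
      }
      return(0)
    }
    num / den
  }
  p <- safe_div(tp, tp + fp, "precision")
  r <- safe_div(tp, tp + fn, "recall")
  f1 <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  c(precision = p, recall = r, f1 = f1)
}

#' Confusion matrix over a label-pair table
#'
#' Counts `counts[t, p]` = number of pairs with true label `t` and predicted
#' label `p`, over the sorted set of labels occurring in the table (entity
#' labels plus `O`). Per-label one-vs-rest counts follow: TP the diagonal,
#' FP the column residue, FN the row residue, TN the rest.
#'
#' @param pairs A [label_pairs()] table.
#' @return A `ner_confusion`: list with `labels`, `counts` (matrix) and
#'   `class_counts` (data frame `label`, `tp`, `fp`, `fn`, `tn`, `support`).
#' @export
confusion_matrix <- function(pairs) {
  pairs <- label_pairs(pairs)
  if (nrow(pairs) == 0L) {
    nerval_stop("empty pair table", class = "nerval_pair_error")
  }
  labels <- sort(unique(c(pairs$y_true, pairs$y_pred)), method = "radix")
  counts <- table(factor(pairs$y_true, levels = labels),
                  factor(pairs$y_pred, levels = labels))
  counts <- matrix(as.integer(counts), nrow = length(labels),
                   dimnames = list(true = labels, pred = labels))
  total <- sum(counts)
  tp <- diag(counts)
  fp <- colSums(counts) - tp
  fn <- rowSums(counts) - tp
  tn <- total - tp - fp - fn
  structure(list(
    labels = labels,
    counts = counts,
    class_counts = data.frame(label = labels, tp = as.integer(tp),
                              fp = as.integer(fp), fn = as.integer(fn),
                              tn = as.integer(tn),
                              support = as.integer(tp + fn),
                              stringsAsFactors = FALSE, row.names = NULL)),
    class = "ner_confusion")
}

#' @export
print.ner_confusion <- function(x, ...) {
  cat("Confusion matrix (rows = true, columns = predicted)\n")
  print(x$counts)
  cat("\n")
  print(x$class_counts, row.names = FALSE)
  invisible(x)
}

score_report <- function(per_label, accuracy, include_O, n_units,
                         regime = "relaxed") {
  macro <- c(precision = mean(per_label$precision),
             recall = mean(per_label$recall),
             f1 = mean(per_label$f1))
  wts <- per_label$support / sum(per_label$support)
  weighted <- c(precision = sum(wts * per_label$precision),
                recall = sum(wts * per_label$recall),
                f1 = sum(wts * per_label$f1))
  structure(list(per_label = per_label, accuracy = accuracy, macro = macro,
                 weighted = weighted, include_O = include_O,
                 n_units = n_units, regime = regime),
            class = "ner_score_report")
}

#' Classification metrics over a label-pair table
#'
#' The relaxed-match score report: per-label precision/recall/F1/support from
#' one-vs-rest confusion counts, overall accuracy (agreeing pairs over all
#' pairs), and macro (unweighted) and weighted (support-weighted) averages
#' over the included labels. `O` rows always enter the accuracy denominator;
#' `include_O` only controls whether `O` appears as a scored class.
#'
#' @param pairs A [label_pairs()] table.
#' @param include_O Score `O` as a class (default `TRUE`, the relaxed-match
#'   convention).
#' @param zero_division Passed to [f1_from_counts()].
#' @return A `ner_score_report`.
#' @export
classification_metrics <- function(pairs, include_O = TRUE,
                                   zero_division = "warn") {
  pairs <- label_pairs(pairs)
  if (nrow(pairs) == 0L) {
    nerval_stop("empty pair table", class = "nerval_pair_error")
  }
  cm <- confusion_matrix(pairs)
  cc <- cm$class_counts
  if (!include_O) cc <- cc[cc$label != o_label(), , drop = FALSE]
  prf <- t(vapply(seq_len(nrow(cc)), function(i) {
    f1_from_counts(cc$tp[i], cc$fp[i], cc$fn[i], zero_division = zero_division)
  }, numeric(3)))
  per_label <- data.frame(label = cc$label,
                          precision = prf[, "precision"],
                          recall = prf[, "recall"],
                          f1 = prf[, "f1"],
                          support = cc$support,
                          stringsAsFactors = FALSE)
  accuracy <- sum(diag(cm$counts)) / sum(cm$counts)
  score_report(per_label, accuracy, include_O = include_O,
               n_units = nrow(pairs), regime = "relaxed")
}

exact_counts_one <- function(ref, pred) {
  if (!identical(ref$text, pred$text)) {
    nerval_stop(sprintf("documents %s / %s have different texts",
                        ref$doc_id, pred$doc_id),
                class = "nerval_alignment_error")
  }
  key <- function(sp) sprintf("%d:%d:%s", sp$start, sp$end, sp$label)
  rk <- key(ref$spans); pk <- key(pred$spans)
  hit <- pk %in% rk
  list(tp_labels = pred$spans$label[hit],
       fp_labels = pred$spans$label[!hit],
       fn_labels = ref$spans$label[!(rk %in% pk)])
}

#' Exact-match metrics over document pairs
#'
#' A predicted span scores as a true positive only when a reference span with
#' identical start, end and label exists; other predicted spans are false
#' positives, unmatched reference spans false negatives. The reported
#' accuracy is the micro ratio `TP / (TP + FP + FN)`.
#'
#' @param reference_docs,predicted_docs Lists of [ner_document]s (or single
#'   documents) over shared texts, paired positionally.
#' @param include_O Recorded in the report; exact matching has no `O` units,
#'   so the default is `FALSE`.
#' @param zero_division Passed to [f1_from_counts()].
#' @return A `ner_score_report`.
#' @export
exact_match_metrics <- function(reference_docs, predicted_docs,
                                include_O = FALSE, zero_division = "warn") {
  if (inherits(reference_docs, "ner_document")) reference_docs <- list(reference_docs)
  if (inherits(predicted_docs, "ner_document")) predicted_docs <- list(predicted_docs)
  stopifnot(length(reference_docs) == length(predicted_docs))
  res <- Map(exact_counts_one, reference_docs, predicted_docs)
  tp_labels <- unlist(lapply(res, `[[`, "tp_labels"))
  fp_labels <- unlist(lapply(res, `[[`, "fp_labels"))
  fn_labels <- unlist(lapply(res, `[[`, "fn_labels"))
  report_from_entity_counts(tp_labels, fp_labels, fn_labels,
                            include_O = include_O,
                            zero_division = zero_division,
                            regime = "exact")
}

report_from_entity_counts <- function(tp_labels, fp_labels, fn_labels,
                                      include_O, zero_division, regime) {
  labels <- sort(unique(c(tp_labels, fp_labels, fn_labels)), method = "radix")
  per_label <- do.call(rbind, lapply(labels, function(L) {
    tp <- sum(tp_labels == L); fp <- sum(fp_labels == L); fn <- sum(fn_labels == L)
    prf <- f1_from_counts(tp, fp, fn, zero_division = zero_division)
    data.frame(label = L, precision = prf["precision"], recall = prf["recall"],
               f1 = prf["f1"], support = tp + fn,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  n_tp <- length(tp_labels); n_fp <- length(fp_labels); n_fn <- length(fn_labels)
  total <- n_tp + n_fp + n_fn
  accuracy <- if (total == 0) 0 else n_tp / total
  if (is.null(per_label)) {
    per_label <- data.frame(label = character(), precision = numeric(),
                            recall = numeric(), f1 = numeric(),
                            support = integer(), stringsAsFactors = FALSE)
    return(structure(list(per_label = per_label, accuracy = accuracy,
                          macro = c(precision = 0, recall = 0, f1 = 0),
                          weighted = c(precision = 0, recall = 0, f1 = 0),
                          include_O = include_O, n_units = total,
                          regime = regime),
                     class = "ner_score_report"))
  }
  score_report(per_label, accuracy, include_O = include_O, n_units = total,
               regime = regime)
}

#' Chunk-based metrics over parallel BIO streams
#'
#' Entity chunks are extracted from the true and predicted BIO sequences; a
#' predicted chunk counts as correct only with identical sequence position,
#' token boundaries and label, as in seqeval-style evaluation. Invalid
#' `I-` transitions are repaired to `B-` by default (lenient mode) with a
#' warning; `strict = TRUE` raises instead.
#'
#' @param true_bio,pred_bio Parallel lists of `bio_sequence`s (equal sequence
#'   and token counts).
#' @param strict Raise on invalid BIO transitions instead of repairing.
#' @param zero_division Passed to [f1_from_counts()].
#' @return A `ner_score_report` (no `O` class; accuracy is the micro
#'   `TP/(TP+FP+FN)` ratio).
#' @export
seqeval_style_metrics <- function(true_bio, pred_bio, strict = FALSE,
                                  zero_division = "warn") {
  stopifnot(length(true_bio) == length(pred_bio))
  tp_labels <- character(0); fp_labels <- character(0); fn_labels <- character(0)
  for (i in seq_along(true_bio)) {
    tt <- true_bio[[i]]$tags; pt <- pred_bio[[i]]$tags
    if (length(tt) != length(pt)) {
      nerval_stop(sprintf("sequence %d: true/pred token counts differ (%d vs %d)",
                          i, length(tt), length(pt)),
                  class = "nerval_bio_error")
    }
    ct <- bio_chunks(tt, repair = !strict)
    cp <- bio_chunks(pt, repair = !strict)
    kt <- sprintf("%d:%d:%s", ct$from, ct$to, ct$label)
    kp <- sprintf("%d:%d:%s", cp$from, cp$to, cp$label)
    hit <- kp %in% kt
    tp_labels <- c(tp_labels, cp$label[hit])
    fp_labels <- c(fp_labels, cp$label[!hit])
    fn_labels <- c(fn_labels, ct$label[!(kt %in% kp)])
  }
  report_from_entity_counts(tp_labels, fp_labels, fn_labels,
                            include_O = FALSE, zero_division = zero_division,
                            regime = "bio")
}
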