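# Bundled reference evaluation counts, and expansion of a printed confusion
# matrix back into the pair multiset that realizes it. A published confusion
# matrix fully determines every pair-based metric, so desk-scale
# recomputation of reported scores needs only these counts.

#' Expand a confusion matrix into a realizing label-pair table
#'
#' Builds a pair multiset with exactly `counts[t, p]` rows of
#' `(y_true = t, y_pred = p)`; running [classification_metrics()] on the
#' result reproduces every metric the matrix determines.
#'
#' @param counts Square integer matrix with identical row/column label names.
#' @return A [label_pairs()] table (surfaces are placeholder tokens).
#' @export
pairs_from_confusion <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == ncol(counts),
            identical(rownames(counts), colnames(counts)))
  labels <- rownames(counts)
  y_true <- character(0); y_pred <- character(0)
  for (t in labels) {
    for (p in labels) {
      n <- counts[t, p]
      if (n > 0) {
        y_true <- c(y_true, rep(t, n))
        y_pred <- c(y_pred, rep(p, n))
      }
    }
  }
  label_pairs(data.frame(doc_id = "confusion", surface = "unit",
                         y_true = y_true, y_pred = y_pred,
                         stringsAsFactors = FALSE))
}

#' Bundled reference evaluation counts
#'
#' The package ships, as plain CSV under `extdata/reference_scores/`, the
#' printed evaluation counts of the many-shot LLM annotation study of
#' Turkish mammography reports whose conventions this package implements:
#' the complete relaxed-match confusion matrix (five entity classes plus
#' `O`, 3434 evaluation units) and the exact-match per-entity TP/FP/FN
#' counts (2454 reference entities). They allow every pair-derived metric of
#' that evaluation to be recomputed from scratch.
#'
#' @return `reference_relaxed_confusion()`: an integer matrix (rows = true,
#'   columns = predicted); `reference_exact_counts()`: a data frame with
#'   columns `label`, `tp`, `fp`, `fn`.
#' @export
reference_relaxed_confusion <- function() {
  path <- system.file("extdata", "reference_scores", "relaxed_confusion.csv",
                      package = "nerval", mustWork = TRUE)
  df <- utils::read.csv(path, check.names = FALSE, row.names = 1)
  m <- as.matrix(df)
  storage.mode(m) <- "integer"
  names(dimnames(m)) <- c("true", "pred")
  m
}

#' @rdname reference_relaxed_confusion
#' @export
reference_exact_counts <- function() {
  path <- system.file("extdata", "reference_scores", "exact_counts.csv",
                      package = "nerval", mustWork = TRUE)
  utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}
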