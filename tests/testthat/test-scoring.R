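test_that("f1_from_counts matches hand-computed ratios and conventions", {
  expect_equal(f1_from_counts(784, 11, 1),
               c(precision = 784 / 795, recall = 784 / 785,
                 f1 = 2 * (784 / 795) * (784 / 785) / (784 / 795 + 784 / 785)))
  expect_equal(round(f1_from_counts(784, 11, 1), 4),
               c(precision = 0.9862, recall = 0.9987, f1 = 0.9924))
  expect_equal(round(f1_from_counts(710, 87, 102)[["f1"]], 4), 0.8825)
  expect_equal(f1_from_counts(0, 0, 0),
               c(precision = 0, recall = 0, f1 = 0))
  expect_warning(f1_from_counts(0, 0, 5, zero_division = "warn"),
                 class = "nerval_zero_division")
  expect_error(f1_from_counts(0, 0, 5, zero_division = "raise"),
               class = "nerval_count_error")
  expect_error(f1_from_counts(-1, 0, 0), class = "nerval_count_error")
})

test_that("confusion matrix counts and one-vs-rest decomposition are consistent", {
  cm <- confusion_matrix(pairs_from_confusion(reference_relaxed_confusion()))
  anat <- cm$class_counts[cm$class_counts$label == "ANAT", ]
  expect_equal(anat$tp, 784L)
  expect_equal(anat$fp, 11L)
  expect_equal(anat$fn, 1L)
  expect_equal(anat$tn, 3434L - 795L - 785L + 784L)  # 2638
  expect_equal(anat$tn, 2638L)
  expect_true(all(rowSums(cm$counts) ==
                    cm$class_counts$tp + cm$class_counts$fn))
  expect_equal(sum(cm$class_counts$tp + cm$class_counts$fp +
                     cm$class_counts$fn + cm$class_counts$tn),
               6L * sum(cm$counts))

  set.seed(5)
  pairs <- label_pairs(data.frame(
    y_true = sample(c(ner_labels(), "O"), 200, replace = TRUE),
    y_pred = sample(c(ner_labels(), "O"), 200, replace = TRUE)))
  cm2 <- confusion_matrix(pairs)
  for (L in cm2$labels) {
    expect_equal(sum(cm2$counts[L, ]), sum(pairs$y_true == L))
    expect_equal(sum(cm2$counts[, L]), sum(pairs$y_pred == L))
  }
  expect_equal(sum(diag(cm2$counts)) / sum(cm2$counts),
               mean(pairs$y_true == pairs$y_pred))
})

test_that("trivial and degenerate pair tables score correctly", {
  one <- classification_metrics(label_pairs(
    data.frame(y_true = "ANAT", y_pred = "ANAT")))
  expect_equal(one$accuracy, 1)
  expect_equal(one$per_label$f1, 1)
  expect_error(classification_metrics(label_pairs(
    data.frame(y_true = character(), y_pred = character()))),
    class = "nerval_pair_error")

  agree <- label_pairs(data.frame(y_true = rep(ner_labels(), 4),
                                  y_pred = rep(ner_labels(), 4)))
  rep_ <- classification_metrics(agree)
  expect_equal(rep_$accuracy, 1)
  expect_true(all(rep_$per_label$f1 == 1))
})

test_that("F1 lies between min and arithmetic mean of precision and recall", {
  set.seed(19)
  for (i in 1:50) {
    cnt <- sample(0:40, 3, replace = TRUE)
    prf <- suppressWarnings(f1_from_counts(cnt[1], cnt[2], cnt[3]))
    expect_gte(prf[["f1"]] + 1e-12, min(prf[["precision"]], prf[["recall"]]))
    expect_lte(prf[["f1"]], (prf[["precision"]] + prf[["recall"]]) / 2 + 1e-12)
  }
})

test_that("exact-match scoring requires identical boundaries and label", {
  doc <- random_doc(4, doc_id = "x")
  perfect <- exact_match_metrics(doc, doc)
  expect_true(all(perfect$per_label$f1 == 1))
  expect_equal(perfect$accuracy, 1)

  set.seed(33)
  shifted <- perturb(doc, perturb_config(p_boundary_shift = 1, max_shift = 2L))
  while (identical(shifted$spans, doc$spans)) {
    shifted <- perturb(doc, perturb_config(p_boundary_shift = 1, max_shift = 2L))
  }
  ex <- exact_match_metrics(doc, shifted)
  rel <- classification_metrics(align_entities(doc, shifted), include_O = FALSE)
  expect_lt(ex$accuracy, 1)
  expect_true(all(rel$per_label$f1 == 1))
})

test_that("relaxed per-label F1 never falls below exact per-label F1", {
  set.seed(61)
  for (i in 1:8) {
    ref <- random_doc(sample(2:6, 1))
    pred <- perturb(ref, perturb_config(p_boundary_shift = 0.6,
                                        p_label_swap = 0.2, p_delete = 0.2,
                                        p_insert = 0.1))
    rel <- suppressWarnings(
      classification_metrics(align_entities(ref, pred), include_O = FALSE))
    ex <- suppressWarnings(exact_match_metrics(ref, pred))
    shared <- intersect(rel$per_label$label, ex$per_label$label)
    for (L in shared) {
      expect_gte(rel$per_label$f1[rel$per_label$label == L] + 1e-12,
                 ex$per_label$f1[ex$per_label$label == L])
    }
  }
})

test_that("BIO chunk scoring agrees with an independent brute-force chunker", {
  set.seed(97)
  for (i in 1:40) {
    n <- sample(1:30, 1)
    true_tags <- random_tags(n, p_dangle = 0.1)
    pred_tags <- random_tags(n, p_dangle = 0.1)
    toks <- rep("w", n)
    got <- suppressWarnings(seqeval_style_metrics(
      list(nerval:::bio_sequence(toks, true_tags)),
      list(nerval:::bio_sequence(toks, pred_tags))))
    ct <- brute_chunks(true_tags); cp <- brute_chunks(pred_tags)
    key <- function(ch) if (is.null(ch)) character(0) else
      paste(ch$from, ch$to, ch$label)
    tp <- length(intersect(key(ct), key(cp)))
    # counts per label from the oracle
    for (L in unique(c(ct$label, cp$label))) {
      kt <- key(ct[ct$label == L, , drop = FALSE])
      kp <- key(cp[cp$label == L, , drop = FALSE])
      tpL <- length(intersect(kt, kp))
      prf <- suppressWarnings(
        f1_from_counts(tpL, length(kp) - tpL, length(kt) - tpL))
      row <- got$per_label[got$per_label$label == L, ]
      expect_equal(row$f1, prf[["f1"]])
      expect_equal(row$precision, prf[["precision"]])
      expect_equal(row$recall, prf[["recall"]])
    }
    expect_equal(got$accuracy,
                 if (length(key(ct)) + length(key(cp)) == 0) 0 else
                   tp / (length(key(ct)) + length(key(cp)) - tp))
  }
})

test_that("all-O streams yield an empty per-label section", {
  got <- seqeval_style_metrics(
    list(nerval:::bio_sequence(c("a", "b"), c("O", "O"))),
    list(nerval:::bio_sequence(c("a", "b"), c("O", "O"))))
  expect_equal(nrow(got$per_label), 0L)
})

test_that("strict mode rejects dangling I- tags, lenient mode repairs them", {
  toks <- c("a", "b")
  bad <- list(nerval:::bio_sequence(toks, c("O", "I-ANAT")))
  good <- list(nerval:::bio_sequence(toks, c("O", "B-ANAT")))
  expect_error(seqeval_style_metrics(bad, good, strict = TRUE),
               class = "nerval_bio_error")
  expect_warning(rep_ <- seqeval_style_metrics(bad, good),
                 class = "nerval_bio_warning")
  expect_equal(rep_$per_label$f1, 1)
})

test_that("report printing rounds half-up to two decimals", {
  expect_identical(nerval:::fmt2(0.995), "1.00")
  expect_identical(nerval:::fmt2(0.98616), "0.99")
  expect_identical(nerval:::fmt2(0.79535), "0.80")
  rep_ <- classification_metrics(pairs_from_confusion(
    reference_relaxed_confusion()))
  out <- format(rep_)
  expect_true(any(grepl("^accuracy\\s+0\\.99\\s+3434$", trimws(out))))
})
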