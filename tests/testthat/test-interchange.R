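test_that("tokenizer splits whitespace and detaches edge punctuation", {
  expect_identical(tokenize("right breast")$surface, c("right", "breast"))
  expect_identical(tokenize("atelectasis -infarction")$surface,
                   c("atelectasis", "-", "infarction"))
  expect_equal(nrow(tokenize("")), 0L)
  expect_equal(nrow(tokenize("   ")), 0L)
  tok <- tokenize("mass (2 cm), stable.")
  expect_identical(tok$surface, c("mass", "(", "2", "cm", ")", ",", "stable", "."))
  # offsets reconstruct the text
  txt <- "a-b, c."
  tok2 <- tokenize(txt)
  expect_identical(substring(txt, tok2$start + 1, tok2$end), tok2$surface)
})

test_that("detach_punctuation frees entity boundaries glued to punctuation", {
  doc <- ner_document("atelectasis -infarction",
                      data.frame(start = 13, end = 23, label = "OBS-P"))
  out <- detach_punctuation(doc)
  expect_identical(out$text, "atelectasis - infarction")
  expect_identical(out$spans$surface, "infarction")

  clean <- ner_document("right breast is normal",
                        data.frame(start = 0, end = 12, label = "ANAT"))
  expect_docs_equal(detach_punctuation(clean), clean)

  set.seed(7)
  for (i in 1:15) {
    d <- random_doc(sample(0:4, 1))
    out <- detach_punctuation(d)
    expect_identical(gsub("\\s", "", out$spans$surface),
                     gsub("\\s", "", d$spans$surface))
    expect_identical(gsub("\\s", "", out$text), gsub("\\s", "", d$text))
  }
})

test_that("JSONL records and documents are bijective", {
  rec <- list(text = "right breast", label = list(list(0, 12, "ANAT")))
  d <- from_jsonl_record(rec)
  expect_identical(d$text, "right breast")
  expect_equal(d$spans$label, "ANAT")

  empty <- ner_document("no findings", NULL, doc_id = "e1")
  expect_length(to_jsonl_record(empty)$label, 0L)

  # Doccano "entities" dialect is read-compatible
  rec2 <- list(text = "right breast",
               entities = list(list(id = 1, label = "ANAT",
                                    start_offset = 0, end_offset = 12)))
  expect_equal(from_jsonl_record(rec2)$spans, d$spans)

  expect_error(from_jsonl_record(list(text = "ab",
                                      label = list(list(0, 9, "ANAT")),
                                      id = "bad1")),
               "bad1", class = "nerval_jsonl_error")

  set.seed(11)
  docs <- lapply(1:10, function(i) random_doc(sample(0:5, 1),
                                              doc_id = paste0("d", i)))
  path <- tempfile(fileext = ".jsonl")
  on.exit(unlink(path))
  write_jsonl(docs, path)
  back <- read_jsonl(path)
  for (i in seq_along(docs)) expect_docs_equal(back[[i]], docs[[i]])
})

test_that("doc_to_bio emits valid tags and decodes back to the spans", {
  d <- ner_document("shows nodular opacities here",
                    data.frame(start = 6, end = 23, label = "OBS-P"))
  bio <- doc_to_bio(d)
  expect_identical(bio$tags[2:3], c("B-OBS-P", "I-OBS-P"))
  expect_true(all(bio$tags[-(2:3)] == "O"))

  plain <- doc_to_bio(ner_document("nothing to report"))
  expect_true(all(plain$tags == "O"))

  set.seed(23)
  for (i in 1:15) {
    doc <- random_doc(sample(0:5, 1))
    bio <- doc_to_bio(doc)
    expect_equal(bio_to_spans(bio), doc$spans[, c("start", "end", "label")])
    # I-L only ever follows B-L / I-L of the same label
    expect_silent(nerval:::bio_chunks(bio$tags, repair = FALSE))
  }
})

test_that("doc_to_bio rejects spans that split a token", {
  d <- ner_document("atelectasis -infarction",
                    data.frame(start = 13, end = 23, label = "OBS-P"))
  # "-infarction" is already split by the package tokenizer, so misalign
  # deliberately mid-word instead
  d2 <- ner_document("abcdef ghi", data.frame(start = 0, end = 3, label = "IMP"))
  expect_error(doc_to_bio(d2), class = "nerval_alignment_error")
  expect_silent(doc_to_bio(d))
})

test_that("pairs_to_bio produces parallel equal-length streams", {
  pairs <- label_pairs(data.frame(
    surface = c("nodular opacities", "axilla", "the"),
    y_true = c("OBS-P", "ANAT", "O"),
    y_pred = c("OBS-P", "O", "IMP")))
  streams <- pairs_to_bio(pairs)
  expect_length(streams$true, 3L)
  expect_identical(streams$true[[1]]$tags, c("B-OBS-P", "I-OBS-P"))
  expect_identical(streams$pred[[1]]$tags, c("B-OBS-P", "I-OBS-P"))
  expect_identical(streams$true[[2]]$tags, "B-ANAT")
  expect_identical(streams$pred[[2]]$tags, "O")
  for (i in 1:3) {
    expect_length(streams$true[[i]]$tags, length(streams$pred[[i]]$tags))
  }
  expect_error(pairs_to_bio(label_pairs(data.frame(
    surface = "", y_true = "ANAT", y_pred = "O"))),
    class = "nerval_pair_error")
})

test_that("pair files round-trip with configurable delimiters and extra columns", {
  pairs <- label_pairs(data.frame(
    doc_id = "r1", surface = c("sol meme", "BIRADS 2", "ve"),
    y_true = c("ANAT", "IMP", "O"), y_pred = c("ANAT", "O", "O"),
    Compare = c(TRUE, FALSE, TRUE)))
  for (delim in c(";", ",")) {
    path <- tempfile(fileext = ".csv")
    write_pairs(pairs, path, delimiter = delim)
    back <- read_pairs(path, delimiter = delim)
    expect_identical(back$y_true, pairs$y_true)
    expect_identical(back$y_pred, pairs$y_pred)
    expect_identical(back$surface, pairs$surface)
    expect_true("Compare" %in% names(back))
    unlink(path)
  }
  bad <- tempfile(fileext = ".csv")
  writeLines("a;b\n1;2", bad)
  expect_error(read_pairs(bad), class = "nerval_pair_error")
  unlink(bad)
})
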