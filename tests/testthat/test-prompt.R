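test_that("prompt assembly follows the fixed component order", {
  spec <- prompt_spec(default_instructions(), default_shots(),
                      target_report = "The right breast is unremarkable.")
  text <- build_prompt(spec)
  trans_at <- regexpr(default_transitional_phrase(), text, fixed = TRUE)
  expect_gt(trans_at, 0)
  # transitional phrase sits immediately before the target
  after <- substring(text, trans_at + attr(trans_at, "match.length"))
  expect_match(after, "^\n\nThe right breast is unremarkable\\.")
  # control phrases close the prompt
  ctrl <- default_control_phrases()
  expect_match(text, paste0(
    "\\Q", ctrl[1], "\\E\n\n\\Q", ctrl[2], "\\E$"), perl = TRUE)
  # instructions open it, shots in authored order in between
  expect_true(startsWith(text, default_instructions()))
  shot1 <- regexpr(spec$shots[[1]]$output_markup, text, fixed = TRUE)
  shot2 <- regexpr(spec$shots[[2]]$output_markup, text, fixed = TRUE)
  expect_true(0 < shot1 && shot1 < shot2 && shot2 < trans_at)
})

test_that("zero-shot prompts and determinism", {
  spec0 <- prompt_spec("Tag the entities.", list(), target_report = "text")
  t0 <- build_prompt(spec0)
  expect_false(grepl("Example", t0, fixed = TRUE))
  spec <- prompt_spec(default_instructions(), default_shots(),
                      target_report = "Same target.")
  expect_identical(build_prompt(spec), build_prompt(spec))
  # seeded shuffle is deterministic, order preserved without it
  sh1 <- prompt_spec(default_instructions(), default_shots(),
                     target_report = "t", shuffle_seed = 4L)
  sh2 <- prompt_spec(default_instructions(), default_shots(),
                     target_report = "t", shuffle_seed = 4L)
  expect_identical(build_prompt(sh1), build_prompt(sh2))
})

test_that("token estimation and budget enforcement", {
  expect_equal(estimate_tokens(""), 0L)
  expect_equal(estimate_tokens(strrep("a", 40)), 10L)
  expect_equal(estimate_tokens("abc"), 1L)
  expect_equal(estimate_tokens("whatever", tokenizer = function(x) 7L), 7L)
  spec <- prompt_spec("Tag entities in the text.", list(),
                      target_report = strrep("report ", 50))
  expect_error(build_prompt(spec, budget = 10),
               class = "nerval_budget_error")
  expect_silent(build_prompt(spec, budget = 10000))
})

test_that("packaged shots round-trip through the markup codec", {
  for (s in default_shots()) {
    doc <- parse_markup(s$output_markup)
    expect_identical(doc$text, s$input_text)
    expect_identical(render_markup(doc), gsub(' class = "', ' class="',
                                              normalize_quotes(s$output_markup)))
  }
  expect_error(shot("other text", '<span class="ANAT">breast</span>'),
               class = "nerval_shot_error")
})

test_that("the default correction rules strip boilerplate mis-annotations", {
  rules <- default_correction_rules()
  expect_equal(nrow(rules), 4L)
  wrong <- rules$wrong[1]
  fixed <- apply_corrections(wrong)
  expect_identical(fixed, rules$corrected[1])
  expect_false(grepl("<span", fixed, fixed = TRUE))
  # typographic quotes in responses are normalized before matching
  curly <- gsub('class = "', 'class = \u201c', wrong)
  curly <- sub('">', '\u201d>', curly)
  expect_identical(apply_corrections(curly), rules$corrected[1])
  # untouched text passes through; application is idempotent
  expect_identical(apply_corrections("no rule matches here"),
                   "no rule matches here")
  once <- apply_corrections(wrong)
  expect_identical(apply_corrections(once), once)
})

test_that("corrections only remove rule-defined tags, never payload text", {
  rules <- default_correction_rules()
  strip_tags <- function(x) gsub("<span[^>]*>|</span>", "", x)
  for (i in seq_len(nrow(rules))) {
    input <- paste0("prefix ", rules$wrong[i], " suffix")
    out <- apply_corrections(input, rules)
    expect_identical(strip_tags(normalize_quotes(input)), out)
  }
})

test_that("correction rule validation rejects degenerate rules", {
  expect_error(correction_rules("", "x"), class = "nerval_rule_error")
  expect_error(correction_rules("a", "a"), class = "nerval_rule_error")
  expect_error(correction_rules("a", "ba"), class = "nerval_rule_error")
  path <- tempfile(fileext = ".csv")
  writeLines(c("wrong;corrected", "bad tag;good tag"), path)
  rules <- read_correction_rules(path)
  expect_identical(apply_corrections("a bad tag here", rules),
                   "a good tag here")
  unlink(path)
})

test_that("annotate_report drives backends, fences and divergence checks", {
  # replay backend returns stored fixtures keyed by doc_id
  fixtures <- list(d1 = "```\n<span class=\"ANAT\">right breast</span>\n```")
  be <- backend_replay(fixtures)
  out <- annotate_report("any prompt", be, doc_id = "d1",
                         target = "right breast")
  expect_identical(out, "<span class=\"ANAT\">right breast</span>")
  expect_error(annotate_report("p", be, doc_id = "missing", retries = 0L),
               class = "nerval_backend_error")

  # identity backend echoes the target unannotated, divergence-free
  spec <- prompt_spec("Tag.", list(), target_report = "clean report text")
  ident <- backend_identity()
  expect_silent(markup <- annotate_report(build_prompt(spec), ident,
                                          target = "clean report text"))
  expect_equal(nrow(parse_markup(markup)$spans), 0L)

  # divergence: response strips to a different text than the target
  expect_warning(
    annotate_report("p", be, doc_id = "d1", target = "left breast"),
    class = "nerval_divergence_warning")

  # flaky backend succeeds within the retry budget
  calls <- 0L
  flaky <- function(prompt, doc_id = NULL) {
    calls <<- calls + 1L
    if (calls < 2L) stop("transient")
    "```\nok text\n```"
  }
  expect_identical(annotate_report("p", flaky, retries = 2L), "ok text")
})

test_that("perturbing backend yields markup whose scored error rate matches", {
  corpus <- generate_corpus(corpus_config(n_docs = 60, seed = 12))
  be <- backend_perturb(corpus, perturb_config(p_label_swap = 0.2), seed = 3L)
  preds <- lapply(corpus, function(d) {
    parse_markup(annotate_report("prompt", be, doc_id = d$doc_id),
                 doc_id = d$doc_id)
  })
  pairs <- align_corpus(corpus, preds)
  ent <- pairs[pairs$y_true != "O", ]
  acc <- mean(ent$y_true == ent$y_pred)
  se <- sqrt(0.8 * 0.2 / nrow(ent))
  expect_lt(abs(acc - 0.8), 3 * se)
})

test_that("prompt config files parse into key-value lists", {
  path <- tempfile(fileext = ".cfg")
  writeLines(c("# comment", "instructions: a.txt", "budget = 26000", ""), path)
  cfg <- read_prompt_config(path)
  expect_identical(cfg$instructions, "a.txt")
  expect_identical(cfg$budget, "26000")
  unlink(path)
})
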