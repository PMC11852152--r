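# Many-shot prompt assembly. A prompt is an ordered concatenation of
# instructions, worked input -> output examples ("shots"), a transitional
# phrase, the target report, and trailing control phrases that force the
# model to answer inside a fenced code block. Assembly is deterministic:
# identical specs yield byte-identical prompts.

#' Default transitional and control phrases
#'
#' The transitional phrase introduces the report to be annotated; the control
#' phrases, appended after it, enforce fenced code-block output in chat
#' interfaces.
#'
#' @return Character scalar / vector.
#' @export
default_transitional_phrase <- function() {
  "Here is the mammography report to be tagged:"
}

#' @rdname default_transitional_phrase
#' @export
default_control_phrases <- function() {
  c("###Do not forget to output in a code snippet window.",
    "###Why didn't you output in a code snippet window?")
}

#' Construct a worked prompt example (shot)
#'
#' A shot couples a raw report sentence with its annotated markup. The
#' markup must strip back to the input text (modulo whitespace
#' normalization), which is checked at construction.
#'
#' @param input_text Raw sentence or section.
#' @param output_markup Its inline HTML-span annotation.
#' @return A `ner_shot` list.
#' @export
shot <- function(input_text, output_markup) {
  input_text <- utf8(input_text)
  output_markup <- utf8(output_markup)
  squash <- function(x) gsub("\\s+", " ", trimws(x))
  stripped <- parse_markup(output_markup, doc_id = "shot")$text
  if (!identical(squash(stripped), squash(input_text))) {
    nerval_stop("shot markup does not strip back to its input text",
                class = "nerval_shot_error")
  }
  structure(list(input_text = input_text, output_markup = output_markup),
            class = "ner_shot")
}

#' Assemble a prompt specification
#'
#' @param instructions Instruction text (task description, markup guidance,
#'   entity definitions, annotation guidelines).
#' @param shots List of [shot()] examples, kept in authored order (use
#'   `shuffle_seed` for a seeded ablation shuffle).
#' @param target_report The report to be annotated.
#' @param transitional_phrase Phrase placed immediately before the target.
#' @param control_phrases Trailing output-format enforcement phrases (may be
#'   empty).
#' @param shuffle_seed Optional integer; when given, shots are shuffled
#'   deterministically under this seed.
#' @return A `prompt_spec` list with a `token_estimate` field for the
#'   assembled prompt.
#' @export
prompt_spec <- function(instructions, shots = list(), target_report,
                        transitional_phrase = default_transitional_phrase(),
                        control_phrases = default_control_phrases(),
                        shuffle_seed = NULL) {
  stopifnot(nzchar(instructions), nzchar(target_report),
            nzchar(transitional_phrase))
  shots <- lapply(shots, function(s) {
    if (inherits(s, "ner_shot")) s else shot(s$input_text, s$output_markup)
  })
  if (!is.null(shuffle_seed)) {
    shots <- with_local_seed(shuffle_seed, sample(shots))
  }
  spec <- structure(list(instructions = utf8(instructions),
                         shots = shots,
                         transitional_phrase = utf8(transitional_phrase),
                         target_report = utf8(target_report),
                         control_phrases = utf8(control_phrases),
                         token_estimate = NA_integer_),
                    class = "prompt_spec")
  spec$token_estimate <- estimate_tokens(assemble_prompt(spec))
  spec
}

assemble_prompt <- function(spec) {
  shot_blocks <- vapply(seq_along(spec$shots), function(i) {
    sprintf("### Example %d\nInput: %s\nOutput: %s", i,
            spec$shots[[i]]$input_text, spec$shots[[i]]$output_markup)
  }, character(1))
  parts <- c(spec$instructions, shot_blocks, spec$transitional_phrase,
             spec$target_report, spec$control_phrases)
  paste(parts[nzchar(parts)], collapse = "\n\n")
}

#' Build the prompt text from a specification
#'
#' Components are concatenated in the fixed order instructions, shots,
#' transitional phrase, target report, control phrases, separated by blank
#' lines. When a token `budget` is given, an estimate above it raises a
#' budget error reporting the overflow.
#'
#' @param spec A [prompt_spec()].
#' @param budget Optional maximum token estimate.
#' @return The prompt text (character scalar).
#' @export
build_prompt <- function(spec, budget = NULL) {
  stopifnot(inherits(spec, "prompt_spec"))
  text <- assemble_prompt(spec)
  est <- estimate_tokens(text)
  if (!is.null(budget) && est > budget) {
    nerval_stop(sprintf(
      "prompt estimate %d tokens exceeds budget %d by %d",
      est, as.integer(budget), est - as.integer(budget)),
      class = "nerval_budget_error")
  }
  text
}

#' Estimate the token count of a text
#'
#' Default heuristic: `ceiling(code_points / 4)`, a standard rough
#' equivalence for subword tokenizers. A caller-supplied tokenizer function
#' (text -> integer) may replace it.
#'
#' @param text Character scalar.
#' @param tokenizer Optional function returning an exact count.
#' @return Integer token estimate.
#' @export
#' @examples
#' estimate_tokens(strrep("a", 40))
estimate_tokens <- function(text, tokenizer = NULL) {
  if (!is.null(tokenizer)) return(as.integer(tokenizer(text)))
  as.integer(ceiling(n_chars(utf8(text)) / 4))
}

#' @export
print.prompt_spec <- function(x, ...) {
  cat(sprintf("<prompt_spec: %d shots, ~%d tokens, %d control phrase(s)>\n",
              length(x$shots), x$token_estimate, length(x$control_phrases)))
  invisible(x)
}

#' Packaged miniature prompt components
#'
#' English-language stand-in components shipped with the package: a compact
#' instruction block (task description, markup guidance, entity definitions,
#' annotation guidelines) and a small shot set whose markup round-trips
#' through the codec. They demonstrate the prompt structure at miniature
#' scale; production prompts are expected to be much larger and are loaded
#' from user files.
#'
#' @return `default_instructions()`: character scalar;
#'   `default_shots()`: list of [shot()]s.
#' @export
default_instructions <- function() {
  path <- system.file("extdata", "prompt", "instructions.txt",
                      package = "nerval", mustWork = TRUE)
  paste(readLines(path, encoding = "UTF-8", warn = FALSE), collapse = "\n")
}

#' @rdname default_instructions
#' @export
default_shots <- function() {
  path <- system.file("extdata", "prompt", "shots.txt",
                      package = "nerval", mustWork = TRUE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  lapply(lines, function(l) shot(parse_markup(l)$text, l))
}

#' Read a key-value prompt configuration file
#'
#' Lines of the form `key: value` (or `key = value`); `#` comments and blank
#' lines ignored. Recognized keys: `instructions`, `shots`, `rules`,
#' `budget`, `backend`, `fixtures`.
#'
#' @param path Config file path.
#' @return Named list of character values.
#' @export
read_prompt_config <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  m <- regmatches(lines, regexec("^([A-Za-z_]+)\\s*[:=]\\s*(.*)$", lines))
  bad <- vapply(m, length, integer(1)) < 3L
  if (any(bad)) {
    nerval_stop(sprintf("malformed config line: %s", lines[bad][1]),
                class = "nerval_config_error")
  }
  stats::setNames(lapply(m, `[`, 3L), vapply(m, `[`, character(1), 2L))
}

#' Annotate one report through a pluggable backend
#'
#' Sends the prompt to a backend (a function `f(prompt, doc_id)` returning
#' response text), retrying on error, and extracts the fenced markup from
#' the response. When the target report is supplied, a response whose
#' stripped text differs from it raises a divergence warning.
#'
#' @param prompt Prompt text (from [build_prompt()]).
#' @param backend Backend function; see [backend_replay()],
#'   [backend_identity()], [backend_perturb()].
#' @param doc_id Identifier forwarded to the backend (replay key).
#' @param target Optional raw target report for divergence checking.
#' @param retries Number of additional attempts after a backend error.
#' @return Markup string.
#' @export
annotate_report <- function(prompt, backend, doc_id = NULL, target = NULL,
                            retries = 1L) {
  stopifnot(is.function(backend))
  response <- NULL
  last_err <- NULL
  for (attempt in seq_len(retries + 1L)) {
    response <- tryCatch(backend(prompt, doc_id), error = function(e) {
      last_err <<- e
      NULL
    })
    if (!is.null(response)) break
  }
  if (is.null(response)) {
    nerval_stop(sprintf("backend failed after %d attempt(s): %s",
                        retries + 1L, conditionMessage(last_err)),
                class = "nerval_backend_error")
  }
  markup <- extract_code_block(response)
  if (!is.null(target)) {
    squash <- function(x) gsub("\\s+", " ", trimws(x))
    stripped <- parse_markup(markup, doc_id = doc_id %||% "doc",
                             allow_unknown = TRUE)$text
    if (!identical(squash(stripped), squash(utf8(target)))) {
      nerval_warn(sprintf(
        "response for %s strips to text different from the target report",
        doc_id %||% "doc"),
        class = "nerval_divergence_warning")
    }
  }
  markup
}
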