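# Rule-based post-correction of model markup: ordered literal substring
# replacements, applied after quote normalization. The shipped default rules
# strip spurious anatomy tags the model tends to place on boilerplate
# Turkish mammography sentences (view-acquisition and
# "read the other side's report" lines).

#' Construct a correction rule set
#'
#' @param wrong Character vector of literal strings to replace (non-empty).
#' @param corrected Parallel vector of replacements; a replacement may not
#'   contain its own `wrong` string (this guarantees idempotence).
#' @return A `correction_rules` data frame.
#' @export
correction_rules <- function(wrong, corrected) {
  wrong <- normalize_quotes(wrong)
  corrected <- normalize_quotes(corrected)
  stopifnot(length(wrong) == length(corrected))
  if (any(!nzchar(wrong))) {
    nerval_stop("empty 'wrong' string in correction rule",
                class = "nerval_rule_error")
  }
  if (any(wrong == corrected)) {
    nerval_stop("correction rule with wrong == corrected",
                class = "nerval_rule_error")
  }
  recontains <- mapply(function(w, c) grepl(w, c, fixed = TRUE),
                       wrong, corrected)
  if (any(recontains)) {
    nerval_stop("a corrected string contains its own wrong string; rule would not be idempotent",
                class = "nerval_rule_error")
  }
  structure(data.frame(wrong = wrong, corrected = corrected,
                       stringsAsFactors = FALSE),
            class = c("correction_rules", "data.frame"))
}

#' Default correction rules
#'
#' Four rules removing an `ANAT` tag wrongly emitted on boilerplate
#' sentences of Turkish mammography reports (left/right view-acquisition
#' lines and the cross-reference recommendation lines).
#'
#' @return A [correction_rules()] data frame.
#' @export
default_correction_rules <- function() {
  views <- " memenin MLO ve CC mammogramlar\u0131 elde olunmu\u015ftur"
  crossref <- " MAMMOGRAF\u0130 RAPORUNUN DA OKUNMASI \u00d6NER\u0130L\u0130R"
  # Turkish characters as \u escapes keep the source ASCII-safe
  sag <- "Sa\u011f"; cap_sag <- "SA\u011e"
  tag <- function(inner, rest) {
    sprintf('<span class = "ANAT">%s</span>%s', inner, rest)
  }
  correction_rules(
    wrong = c(tag("Sol memenin", views),
              tag(paste(sag, "memenin"), views),
              tag(cap_sag, crossref),
              tag("SOL", crossref)),
    corrected = c(paste0("Sol memenin", views),
                  paste0(sag, " memenin", views),
                  paste0(cap_sag, crossref),
                  paste0("SOL", crossref)))
}

#' Read user correction rules from a delimited file
#'
#' Expects columns `wrong` and `corrected`. User rules are conventionally
#' appended after the defaults:
#' `rbind(default_correction_rules(), read_correction_rules(path))`.
#'
#' @param path File path.
#' @param delimiter Field separator (default `";"`, since rules routinely
#'   contain commas).
#' @return A [correction_rules()] data frame.
#' @export
read_correction_rules <- function(path, delimiter = ";") {
  df <- utils::read.csv(path, sep = delimiter, check.names = FALSE,
                        colClasses = "character", fileEncoding = "UTF-8")
  if (!all(c("wrong", "corrected") %in% names(df))) {
    nerval_stop(sprintf("file %s lacks wrong/corrected columns", path),
                class = "nerval_rule_error")
  }
  correction_rules(df$wrong, df$corrected)
}

#' Apply correction rules to markup
#'
#' Rules are applied in order as literal substring replacements over the
#' whole (quote-normalized) text. Application is idempotent: running the
#' result through the same rules changes nothing.
#'
#' @param markup Markup text.
#' @param rules A [correction_rules()] data frame (defaults to the packaged
#'   rule set).
#' @return Corrected markup.
#' @export
apply_corrections <- function(markup, rules = default_correction_rules()) {
  out <- normalize_quotes(markup)
  for (i in seq_len(nrow(rules))) {
    out <- gsub(rules$wrong[i], rules$corrected[i], out, fixed = TRUE)
  }
  out
}
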