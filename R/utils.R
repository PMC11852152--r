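#' @keywords internal
"_PACKAGE"

# Internal helpers shared across modules. All text handling is in UTF-8 and
# all offsets are counted in Unicode code points (R character semantics on
# UTF-8 marked strings).

utf8 <- function(x) {
  x <- enc2utf8(as.character(x))
  x
}

n_chars <- function(x) nchar(x, type = "chars")

substr_cp <- function(x, start, end) {
  # start/end are 0-based half-open code-point offsets (vectorized)
  substring(x, start + 1L, end)
}

#' Normalize typographic quotes to their ASCII forms
#'
#' Curly double and single quotes (and their low-9 variants) are mapped to
#' straight `"` and `'`. Applied before markup parsing and before
#' correction-rule matching, since annotation excerpts and rule files are
#' frequently typeset with typographic quotes.
#'
#' @param x Character vector.
#' @return Character vector with quotes normalized, encoded as UTF-8.
#' @export
#' @examples
#' normalize_quotes("class = \u201cANAT\u201d")
normalize_quotes <- function(x) {
  x <- utf8(x)
  x <- gsub("[\u201c\u201d\u201e\u00ab\u00bb]", "\"", x)
  x <- gsub("[\u2018\u2019\u201a\u2039\u203a]", "'", x)
  x
}

# Half-up rounding used for report display (base round() is banker's).
round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

nerval_stop <- function(msg, class, ...) {
  stop(errorCondition(msg, ..., class = c(class, "nerval_error")))
}

nerval_warn <- function(msg, class = "nerval_warning") {
  warning(warningCondition(msg, class = c(class, "nerval_warning")))
}

# Run code with a locally seeded RNG, restoring global RNG state afterwards.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
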