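# Synthetic annotated-report generator. Documents mimic the structure of
# sectioned mammography reports (technique line, findings sentences,
# impression line) with slot-filled entity phrases; entity labels are drawn
# i.i.d. from the configured frequency profile, whose default is
# proportional to the entity supports of the reference evaluation
# (ANAT 785, IMP 345, OBS-A 366, OBS-P 732, OBS-U 122). Text is synthetic
# throughout; no real report text is reproduced.

#' Default entity-frequency profile
#'
#' Proportional to the per-entity supports of the bundled reference
#' evaluation.
#'
#' @return Named numeric vector over [ner_labels()].
#' @export
default_label_weights <- function() {
  c(ANAT = 785, IMP = 345, `OBS-P` = 732, `OBS-A` = 366, `OBS-U` = 122)
}

#' Synthetic corpus configuration
#'
#' @param n_docs Number of documents (>= 1).
#' @param label_weights Positive entity-frequency weights, named by
#'   [ner_labels()]; normalized internally.
#' @param sentences_per_doc Integer range (length 2) of findings sentences
#'   per document.
#' @param entities_per_sentence Integer range of entity slots per sentence.
#' @param template_set `"english"` or `"turkish"` phrase bank.
#' @param seed Integer seed; the same seed yields a byte-identical corpus.
#' @return A `corpus_config` list.
#' @export
corpus_config <- function(n_docs = 10L,
                          label_weights = default_label_weights(),
                          sentences_per_doc = c(2L, 5L),
                          entities_per_sentence = c(1L, 3L),
                          template_set = c("english", "turkish"),
                          seed = 1L) {
  template_set <- match.arg(template_set)
  if (n_docs < 1L) {
    nerval_stop("n_docs must be >= 1", class = "nerval_config_error")
  }
  if (!setequal(names(label_weights), ner_labels()) || any(label_weights <= 0)) {
    nerval_stop("label_weights must be positive and named by the five entity labels",
                class = "nerval_config_error")
  }
  structure(list(n_docs = as.integer(n_docs),
                 label_weights = label_weights[ner_labels()],
                 sentences_per_doc = as.integer(sentences_per_doc),
                 entities_per_sentence = as.integer(entities_per_sentence),
                 template_set = template_set,
                 seed = as.integer(seed)),
            class = "corpus_config")
}

phrase_bank <- function(template_set) {
  if (template_set == "english") {
    list(
      ANAT = c("right breast", "left breast", "upper outer quadrant",
               "left axilla", "retroareolar region", "both breasts",
               "skin and nipple", "right axillary tail"),
      IMP = c("BIRADS 2", "BIRADS 3", "BIRADS 4", "benign appearance",
              "short-interval follow-up is recommended",
              "biopsy is recommended"),
      `OBS-P` = c("nodular opacity", "a spiculated mass",
                  "grouped microcalcifications", "focal asymmetry",
                  "increased parenchymal density", "an irregular mass"),
      `OBS-A` = c("no suspicious mass", "no pathologic microcalcification",
                  "no significant interval change", "no lymphadenopathy",
                  "no skin thickening"),
      `OBS-U` = c("a possible architectural distortion",
                  "an asymmetry that may represent summation",
                  "a questionable focal density"),
      header = c("BILATERAL DIGITAL MAMMOGRAPHY",
                 "SCREENING MAMMOGRAPHY REPORT"),
      technique = c("Standard MLO and CC views were obtained.",
                    "Comparison was made with the prior examination."),
      connect = c("In the", "Within the", "Projecting over the"),
      verb = c("there is", "we note", "examination shows"),
      impression_lead = c("IMPRESSION:", "ASSESSMENT:"))
  } else {
    list(
      ANAT = c("sa\u011f meme", "sol meme", "her iki meme", "sol aksilla",
               "retroareoler b\u00f6lge", "\u00fcst d\u0131\u015f kadran"),
      IMP = c("BIRADS 2", "BIRADS 3", "BIRADS 4", "kontrol \u00f6nerilir",
              "biyopsi \u00f6nerilir"),
      `OBS-P` = c("nod\u00fcler opasite", "spik\u00fcle kitle",
                  "grupla\u015fm\u0131\u015f mikrokalsifikasyonlar", "fokal asimetri"),
      `OBS-A` = c("\u015f\u00fcpheli kitle izlenmemi\u015ftir",
                  "patolojik mikrokalsifikasyon izlenmemi\u015ftir",
                  "belirgin de\u011fi\u015fiklik saptanmam\u0131\u015ft\u0131r"),
      `OBS-U` = c("asimetrik dansite olas\u0131l\u0131\u011f\u0131",
                  "ku\u015fkulu yap\u0131sal distorsiyon"),
      header = c("BILATERAL DIJITAL MAMMOGRAFI"),
      technique = c("MLO ve CC mammogramlar elde olunmu\u015ftur.",
                    "\u00d6nceki tetkik ile kar\u015f\u0131la\u015ft\u0131r\u0131lm\u0131\u015ft\u0131r."),
      connect = c("izlenen", "tariflenen", "mevcut olan"),
      verb = c("saptanm\u0131\u015ft\u0131r", "izlenmektedir", "dikkati \u00e7ekmi\u015ftir"),
      impression_lead = c("SONU\u00c7:", "DE\u011eERLEND\u0130RME:"))
  }
}

sample_range <- function(rng) {
  if (rng[1] == rng[2]) rng[1]
  else rng[1] + sample.int(rng[2] - rng[1] + 1L, 1L) - 1L
}

# Build one sentence, appending to a growing document. Returns list(text,
# spans): entity phrases inserted at recorded offsets.
build_sentence <- function(bank, weights, n_entities, offset) {
  piece <- character(0)
  pos <- offset
  starts <- integer(0); ends <- integer(0); labs <- character(0)
  emit <- function(txt) {
    piece <<- c(piece, txt)
    pos <<- pos + n_chars(txt)
  }
  for (k in seq_len(n_entities)) {
    lead <- if (k == 1L) sample(bank$connect, 1L) else sample(bank$verb, 1L)
    emit(paste0(lead, " "))
    lab <- sample(names(weights), 1L, prob = weights)
    phrase <- sample(bank[[lab]], 1L)
    starts <- c(starts, pos)
    emit(phrase)
    ends <- c(ends, pos)
    labs <- c(labs, lab)
    emit(if (k < n_entities) " " else ".")
  }
  list(text = paste(piece, collapse = ""),
       spans = data.frame(start = starts, end = ends, label = labs,
                          stringsAsFactors = FALSE))
}

#' Generate a synthetic annotated corpus
#'
#' Deterministic under `config$seed`: the same configuration yields a
#' byte-identical corpus. Empirical entity-label frequencies converge to
#' `config$label_weights` as the corpus grows (labels are drawn i.i.d. from
#' the normalized weights).
#'
#' @param config A [corpus_config()].
#' @return List of [ner_document]s with ids `doc001`, `doc002`, ...
#' @export
#' @examples
#' corpus <- generate_corpus(corpus_config(n_docs = 2, seed = 42))
#' corpus[[1]]
generate_corpus <- function(config = corpus_config()) {
  bank <- phrase_bank(config$template_set)
  weights <- config$label_weights / sum(config$label_weights)
  with_local_seed(config$seed, {
    lapply(seq_len(config$n_docs), function(d) {
      header <- paste0(sample(bank$header, 1L), "\n",
                       sample(bank$technique, 1L), "\n")
      text <- header
      spans <- NULL
      n_sent <- sample_range(config$sentences_per_doc)
      for (s in seq_len(n_sent)) {
        lead_in <- if (s == n_sent) {
          paste0("\n", sample(bank$impression_lead, 1L), " ")
        } else ""
        text <- paste0(text, lead_in)
        sent <- build_sentence(bank, weights,
                               sample_range(config$entities_per_sentence),
                               n_chars(text))
        text <- paste0(text, sent$text, if (s < n_sent) " " else "")
        spans <- rbind(spans, sent$spans)
      }
      ner_document(text, spans, doc_id = sprintf("doc%03d", d))
    })
  })
}
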