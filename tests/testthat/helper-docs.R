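# Test fixtures and independent oracles, built in code.
#
# random_doc() is a deliberately naive document generator, independent of
# the package's synthetic_corpus module, used for codec/alignment property
# tests.

random_doc <- function(n_spans = 3L, n_words = 25L, doc_id = "rnd") {
  words <- replicate(n_words, paste(sample(letters, sample(2:8, 1),
                                           replace = TRUE), collapse = ""))
  text <- paste(words, collapse = " ")
  # word k occupies [starts[k], ends[k])
  lens <- nchar(words)
  ends <- cumsum(lens + 1L) - 1L
  starts <- ends - lens
  spans <- NULL
  if (n_spans > 0L) {
    first <- sort(sample(seq_len(n_words), n_spans))
    used_until <- -1L
    for (f in first) {
      if (f <= used_until) next
      last <- min(f + sample(0:2, 1), n_words)
      spans <- rbind(spans, data.frame(start = starts[f], end = ends[last],
                                       label = sample(ner_labels(), 1)))
      used_until <- last
    }
  }
  ner_document(text, spans, doc_id = doc_id)
}

# Exhaustive maximum-total-overlap matcher: enumerates every injective
# assignment of reference spans to overlapping predicted spans and keeps the
# one with the largest total overlap, breaking ties by the lexicographically
# smallest assignment vector. Written as plain enumeration, independent of
# the package's component-decomposition search.
brute_force_assignment <- function(ref, pred, overlap_rule = 1L) {
  rs <- ref$spans; ps <- pred$spans
  n <- nrow(rs); m <- nrow(ps)
  ov <- function(i, j) {
    max(0L, min(rs$end[i], ps$end[j]) - max(rs$start[i], ps$start[j]))
  }
  cands <- lapply(seq_len(n), function(i) {
    js <- if (m == 0L) integer(0) else which(vapply(seq_len(m), function(j)
      ov(i, j) >= overlap_rule, logical(1)))
    c(js, NA_integer_)
  })
  grid <- do.call(expand.grid, c(cands, list(stringsAsFactors = FALSE)))
  best_total <- -1; best <- rep(NA_integer_, n)
  for (r in seq_len(nrow(grid))) {
    a <- as.integer(unlist(grid[r, ], use.names = FALSE))
    picked <- a[!is.na(a)]
    if (anyDuplicated(picked)) next
    total <- sum(vapply(seq_len(n), function(i)
      if (is.na(a[i])) 0L else ov(i, a[i]), integer(1)))
    if (total > best_total) {
      best_total <- total; best <- a
    } else if (total == best_total) {
      av <- ifelse(is.na(a), Inf, a); bv <- ifelse(is.na(best), Inf, best)
      d <- which(av != bv)
      if (length(d) > 0L && av[d[1]] < bv[d[1]]) best <- a
    }
  }
  best
}

# Label-pair multiset implied by an assignment (entity rows only).
pairs_from_assignment <- function(ref, pred, assign) {
  rs <- ref$spans; ps <- pred$spans
  out <- character(0)
  for (i in seq_len(nrow(rs))) {
    p <- if (is.na(assign[i])) "O" else ps$label[assign[i]]
    out <- c(out, paste(rs$label[i], p))
  }
  for (j in setdiff(seq_len(nrow(ps)), assign[!is.na(assign)])) {
    out <- c(out, paste("O", ps$label[j]))
  }
  sort(out)
}

# Independent brute-force BIO chunker mirroring lenient repair semantics:
# a chunk starts at any B- tag or at an I- tag not preceded by a same-type
# B-/I- tag, and extends over following same-type I- tags.
brute_chunks <- function(tags) {
  type <- ifelse(tags == "O", NA_character_, substring(tags, 3L))
  out <- NULL
  i <- 1L
  while (i <= length(tags)) {
    if (!is.na(type[i]) &&
        (startsWith(tags[i], "B-") || i == 1L || is.na(type[i - 1L]) ||
         type[i - 1L] != type[i] || FALSE)) {
      j <- i
      while (j + 1L <= length(tags) && startsWith(tags[j + 1L], "I-") &&
             !is.na(type[j + 1L]) && type[j + 1L] == type[i]) {
        j <- j + 1L
      }
      out <- rbind(out, data.frame(from = i, to = j, label = type[i]))
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  out
}

# Random BIO tag vector (valid or with injected dangling I- tags).
random_tags <- function(n, p_entity = 0.4, p_dangle = 0) {
  tags <- character(n)
  i <- 1L
  while (i <= n) {
    if (stats::runif(1) < p_entity) {
      lab <- sample(ner_labels(), 1)
      len <- sample(1:3, 1)
      len <- min(len, n - i + 1L)
      tags[i:(i + len - 1L)] <- c(paste0("B-", lab),
                                  rep(paste0("I-", lab), len - 1L))
      i <- i + len
    } else {
      tags[i] <- "O"
      i <- i + 1L
    }
  }
  if (p_dangle > 0) {
    flip <- which(startsWith(tags, "B-") & stats::runif(n) < p_dangle)
    tags[flip] <- sub("^B-", "I-", tags[flip])
  }
  tags
}

expect_docs_equal <- function(a, b) {
  expect_identical(a$text, b$text)
  expect_identical(a$doc_id, b$doc_id)
  expect_equal(a$spans, b$spans)
}
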