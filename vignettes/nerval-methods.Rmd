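---
title: "Relaxed and exact evaluation of span-based clinical NER"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Relaxed and exact evaluation of span-based clinical NER}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nerval)
```

## The problem

Large language models can annotate clinical reports by rewriting them with
inline HTML span tags — `<span class="OBS-P">nodular opacity</span>` — given
a prompt that carries instructions and a large bank of worked examples
("shots"). nerval provides the offline machinery around that workflow for
the five-class mammography schema: anatomy (`ANAT`), impression (`IMP`),
and observations reported as present (`OBS-P`), absent (`OBS-A`) or
uncertain (`OBS-U`), with `O` marking non-entity text. It parses and renders
the markup, converts between annotation formats, aligns predictions with
references, scores them under two matching regimes, assembles many-shot
prompts, applies rule-based output corrections, and generates synthetic
annotated corpora so every stage can be tested without real patient data.

All offsets are 0-based, half-open, and counted in Unicode code points; text
is never case-folded, so Turkish dotted/dotless `i` distinctions survive
every conversion.

## Matching regimes

Evaluation reduces each document pair (reference annotation, predicted
annotation) to per-class counts, from which

$$P = \frac{TP}{TP+FP}, \qquad R = \frac{TP}{TP+FN}, \qquad
F_1 = \frac{2PR}{P+R}$$

with the usual convention that a zero denominator yields 0 (a warning is
emitted; `zero_division = "raise"` is available).

**Exact match** (`exact_match_metrics()`): a predicted span is a true
positive only if a reference span with identical start, end and label
exists. The reported accuracy is the micro ratio `TP / (TP + FP + FN)`.

**Relaxed match** (`align_entities()` + `classification_metrics()`): a
predicted span may pair with a reference span of any label as long as they
share at least `overlap_rule` characters (default 1). Each matched pair
contributes one `(true label, predicted label)` row — so a boundary-sloppy
but correctly typed prediction counts as correct, and a typed confusion
lands in the corresponding off-diagonal confusion-matrix cell. Unmatched
reference spans become `(label, O)` rows, unmatched predictions `(O,
label)`, and text unannotated on both sides contributes agreeing `(O, O)`
rows. Relaxed per-label F1 therefore never falls below exact per-label F1,
a property the test suite checks on perturbed corpora.

**Chunk-based BIO scoring** (`seqeval_style_metrics()`) reproduces the
third conventional route: label-pair tables are expanded into parallel BIO
streams (`pairs_to_bio()`), chunks are extracted, and a chunk scores only
on identical boundaries and label. Invalid `I-` transitions are repaired by
promotion to `B-` (the lenient default of common chunk evaluators); strict
mode raises instead.

## The alignment procedure

The pairing of predicted with reference spans is a one-to-one matching that
maximizes total overlapped characters. A simpler greedy pass (largest
overlap first) was considered and rejected: because spans within a document
are disjoint intervals, a predicted span straddling two reference spans can
greedily consume the wrong partner and block a strictly better assignment
(reference spans `[0,10)`, `[10,20)` against predictions `[8,15)`,
`[15,20)` is a minimal counterexample: greedy pairs `[10,20)` with
`[8,15)` for 5 shared characters, while the optimum pairs the four spans
for 7). Disjointness keeps the bipartite overlap graph in small connected
components — chains of straddling spans — so each component is solved
exactly by depth-first search; the test suite checks equality against an
independent exhaustive enumerator.

Ties in total overlap are broken deterministically by the
lexicographically smallest predicted-index assignment in reference order,
which also keeps alignment symmetric: swapping the two documents transposes
the confusion matrix.

The granularity of the `(O, O)` units is genuinely underdetermined by the
conventions this package follows — published totals do not pin down whether
unannotated text was counted per token or per stretch. The package defaults
to one unit per token (`o_unit = "token"`), which matches the way
unannotated tokens enter classification reports, and offers `o_unit =
"run"` as the coarser alternative. O-unit granularity affects only the `O`
row and the accuracy denominator, never the entity rows.

## Scoring conventions

* `include_O` defaults to `TRUE` for relaxed scoring (the `O` class is part
  of the report) and `FALSE` for exact scoring (there are no `O` spans).
  Accuracy always counts all evaluation units; `include_O` only selects the
  scored classes for per-label rows and averages.
* Macro averages are unweighted means over the included labels; weighted
  averages use support weights that sum to 1 over the included labels.
* Displayed values are rounded half-up to two decimals; the underlying
  objects and all JSON output keep full precision. Half-up is chosen over
  base R's banker's rounding because it reproduces the printed convention
  of classification-report tooling. One consequence is documented rather
  than hidden: the bundled exact-match counts for `IMP` (TP 307, FP 75,
  FN 83) give F1 = 0.7953, which displays as 0.80 even though the source
  tabulation printed 0.79.

## The bundled reference counts

`reference_relaxed_confusion()` and `reference_exact_counts()` ship the
printed evaluation counts of the many-shot Turkish mammography study whose
conventions this package implements: a complete 6-by-6 relaxed-match
confusion matrix over 3434 evaluation units and per-entity exact-match
TP/FP/FN over 2454 reference entities. Because a confusion matrix fully
determines every pair-derived metric, `pairs_from_confusion()` can expand
it back into a realizing pair multiset and the whole relaxed score report
can be recomputed from scratch in well under a second; the acceptance
script does exactly that.

## Tokenization and punctuation detachment

The tokenizer splits on whitespace and peels leading/trailing Unicode
punctuation into standalone tokens, reproducing the preprocessing that
token-level pipelines need when punctuation abuts an entity
(`"atelectasis -infarction"` must tokenize as `atelectasis`, `-`,
`infarction`). `detach_punctuation()` inserts a space wherever a span
boundary touches an adjacent punctuation character and remaps offsets, so
every span surface is preserved; it is required only upstream of
exact-match tokenized evaluation. No language-specific (morphological)
tokenization is attempted — that is deliberately out of scope.

## Prompt assembly

A prompt is the deterministic concatenation, separated by blank lines, of:
instructions, numbered shots (`Input:` / `Output:` blocks), the
transitional phrase `"Here is the mammography report to be tagged:"`, the
target report, and trailing control phrases that force fenced code-block
output. Shots are kept in authored order; a seeded shuffle exists for
ablation only. Token budgets are checked with the standard rough heuristic
of one token per four code points, `ceiling(nchar(text)/4)`; an exact
tokenizer can be plugged in, and the budget check reports the overflow
rather than truncating. The packaged instruction block and shot set are
miniature English stand-ins that demonstrate the structure — production
prompts of tens of thousands of tokens are expected to be supplied by the
user as component files, since prompts of that size are corpus-specific.

Backends are stateless functions `f(prompt, doc_id)` returning response
text. The package ships replay (stored fixtures), identity (echoes the
target untagged) and perturbing (known reference plus injected errors)
backends; live API adapters satisfy the same contract but are intentionally
outside the test surface, keeping the whole package runnable offline.
Responses pass through `extract_code_block()`, which takes the interior of
the first triple-backtick fence (any language word accepted, since fence
dialects vary across chat interfaces) and falls back to the whole response
with a warning.

Rule-based corrections are ordered literal replacements applied after
typographic-quote normalization; a rule may not reproduce its own trigger,
which makes application idempotent by construction. The default rules strip
a spurious `ANAT` tag from four boilerplate Turkish report sentences.

## The synthetic corpus and its error model

`generate_corpus()` emits sectioned mammography-style documents (header,
technique line, findings sentences, impression line) with entity phrases
drawn from English or Turkish phrase banks. Entity labels are i.i.d. draws
from a frequency profile whose default is proportional to the reference
supports (785/345/732/366/122), so empirical frequencies converge to the
profile — the suite checks agreement within three binomial standard errors
at about 2800 spans. Defaults of 2–5 findings sentences and 1–3 entities
per sentence give roughly seven spans per document, in line with short
screening reports.

What the generator does *not* emulate: discourse-level coreference, real
clinical phrase co-occurrence statistics, negation scope ambiguity,
misspellings, or report-length variation beyond the configured ranges.
Passing tests on synthetic corpora therefore validate the *evaluation
machinery* — offsets, conversions, matching, counting — not model quality
on real reports.

`perturb()` injects controlled errors with per-span probabilities: deletion,
label swap (uniform over the other four labels), and boundary shift of up
to `max_shift` characters clamped so each span keeps at least one character
of its original extent and never collides with a neighbor (each span may
claim at most half of the gap to its neighbor, so simultaneous shifts
cannot overlap). Spurious single-token spans are inserted over text
unannotated in both the original and perturbed document, guaranteeing they
align to clean `(O, label)` rows. Each span consumes a fixed number of RNG
draws in document order, so a fixed seed replays exactly, and the
end-to-end loop (generate, perturb, align, score) recovers the planted
rates: swap rate `eps` appears as per-label relaxed recall `1 - eps`,
deletion rate as the share of `(label, O)` rows, and boundary-only
perturbation yields relaxed F1 exactly 1 with exact-match accuracy well
below 1.

## Problem sizes and reproducibility

The test suite and the acceptance script run at desk scale by design:
reference-table reproduction is exact arithmetic on 3434 units; property
tests use 30–40 randomized small documents per invariant; recovery tests
use 150-document corpora (about 1000 spans), where three binomial standard
errors give a tolerance of about ±0.03 on a rate of 0.1. All randomness
flows through explicit integer seeds (R's default Mersenne-Twister via
`set.seed()`, restored after use), so corpora, prompts and reports are
byte-identical across runs and platforms.

## Known limitations

* The markup dialect is intentionally flat: one tag type, one class
  attribute, no nesting, no HTML entities. Nested spans are an error, not a
  flattening.
* Greedy users of `o_unit = "token"` should not expect the `O` support of
  any particular external tabulation to be reproduced exactly on real data;
  the granularity that produced a published `O` count is generally
  unknowable from the count alone.
* `estimate_tokens()` is a heuristic; budget decisions near the limit of a
  real model's context window should use that model's tokenizer through the
  plug-in interface.
* Exact-match evaluation here compares span sets directly; it does not
  train or emulate a token-tagger, so tagger-specific effects (tokenizer
  mismatches, subword artifacts) are out of scope.
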