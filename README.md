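# nerval

Offline tooling for evaluating prompt-based named entity recognition (NER)
on span-annotated clinical reports, built around the five-class mammography
schema: anatomy (`ANAT`), impression (`IMP`), and observations present
(`OBS-P`), absent (`OBS-A`) or uncertain (`OBS-U`), with `O` for non-entity
text. It is aimed at clinical NLP practitioners who annotate radiology
reports with large language models via inline HTML span markup
(`<span class="OBS-P">nodular opacity</span>`) and need the surrounding
machinery to be reproducible without network access or real patient data:

* **markup codec** — parse/render inline span markup with exact code-point
  offsets; extract fenced payloads from model responses
  (`parse_markup()`, `render_markup()`, `extract_code_block()`);
* **interchange** — Doccano-style JSONL, two-column BIO files, delimited
  label-pair tables, whitespace/punctuation tokenization
  (`read_jsonl()`, `doc_to_bio()`, `read_pairs()`, `detach_punctuation()`);
* **alignment** — overlap-based one-to-one matching of predicted against
  reference spans, including `(O, O)` units for unannotated text
  (`align_entities()`);
* **scoring** — per-label precision/recall/F1/support, accuracy,
  macro/weighted averages, confusion matrices with TP/FP/FN/TN, under
  relaxed (overlap) and exact (identical boundary) regimes plus chunk-based
  BIO scoring (`classification_metrics()`, `exact_match_metrics()`,
  `seqeval_style_metrics()`);
* **prompting** — deterministic many-shot prompt assembly with token
  budgets, pluggable offline backends (replay/identity/perturbing) and
  rule-based output correction (`build_prompt()`, `annotate_report()`,
  `apply_corrections()`);
* **synthetic corpora** — seeded mammography-style report generation with
  controlled error injection for end-to-end testing
  (`generate_corpus()`, `perturb()`);
* **CLI** — `convert`, `align`, `score`, `build-prompt`, `correct`,
  `annotate`, `simulate` subcommands over the same functions
  (`nerval_cli()`; wrapper script in `inst/cli/nerval`).

## The core statistic

Every regime reduces to per-class counts and

    P = TP / (TP + FP),   R = TP / (TP + FN),   F1 = 2PR / (P + R)

with zero denominators scoring 0. Under **exact** matching a predicted span
must agree on start, end and label. Under **relaxed** matching a predicted
span is paired with a reference span when their character ranges overlap
and contributes a `(true label, predicted label)` row; missed references
yield `(label, O)`, spurious predictions `(O, label)`, and mutually
unannotated tokens `(O, O)`. Pairing maximizes total character overlap
(solved exactly per connected component of the overlap graph) with a
deterministic lexicographic tie-break. See the methods vignette
(`vignettes/nerval-methods.Rmd`) for conventions, design decisions and
limitations.

## Worked example

```r
library(nerval)

markup <- '<span class="ANAT">Sol meme</span> alt kadranda <span class="OBS-P">noduler opasite</span> izlendi.'
doc <- parse_markup(markup, doc_id = "r1")
doc
#> <ner_document r1: 46 chars, 2 spans>
#>   start end label         surface
#> 1     0   8  ANAT        Sol meme
#> 2    22  37 OBS-P noduler opasite

# a prediction with a sloppy boundary (still ANAT) and a label confusion
pred <- ner_document(doc$text,
                     data.frame(start = c(0, 23), end = c(8, 38),
                                label = c("ANAT", "OBS-U")),
                     doc_id = "r1")
align_entities(doc, pred)
#>   doc_id         surface y_true y_pred Compare
#> 1     r1        Sol meme   ANAT   ANAT    TRUE
#> 2     r1             alt      O      O    TRUE
#> 3     r1        kadranda      O      O    TRUE
#> 4     r1 noduler opasite  OBS-P  OBS-U   FALSE
#> 5     r1         izlendi      O      O    TRUE
#> 6     r1               .      O      O    TRUE
```

The first row shows relaxed matching at work: the boundary-shifted `ANAT`
prediction still counts as correct because it overlaps the reference span;
the `OBS-P`/`OBS-U` row is a typed confusion that will land in the
off-diagonal confusion-matrix cell.

Scoring the reference confusion matrix bundled with the package (the
complete relaxed-match tabulation of a many-shot LLM annotation study of
Turkish mammography reports, 3434 evaluation units) reproduces its score
report from raw counts:

```r
rel <- classification_metrics(pairs_from_confusion(reference_relaxed_confusion()))
rel
#> Relaxed-match score report (3434 evaluation units)
#>
#>               precision    recall  f1-score   support
#> ANAT               0.99      1.00      0.99       785
#> IMP                1.00      0.98      0.99       345
#> O                  1.00      0.99      0.99      1084
#> OBS-A              0.99      1.00      1.00       366
#> OBS-P              0.99      1.00      1.00       732
#> OBS-U              0.99      0.98      0.99       122
#>
#> accuracy                               0.99      3434
#> macro avg          0.99      0.99      0.99      3434
#> weighted avg       0.99      0.99      0.99      3434
```

Displayed values are rounded half-up to two decimals; the objects (and all
JSON written by `write_score_report()`) keep full precision.

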