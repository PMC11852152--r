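Package: nerval
Title: Span-Based Clinical Named Entity Recognition Evaluation and Prompt Tooling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating prompt-based named entity recognition on
    span-annotated clinical reports, built around a five-class mammography
    schema (anatomy, impression, observation present/absent/uncertain).
    Provides a codec for inline HTML-span entity markup, interchange between
    annotated documents, JSONL annotation records, tokenized BIO sequences and
    label-pair tables, overlap-based relaxed-match alignment, relaxed and
    exact scoring with confusion matrices, many-shot prompt assembly with
    rule-based output correction and pluggable offline annotation backends,
    and a synthetic annotated-report generator with controlled error
    injection for end-to-end testing without real patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
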