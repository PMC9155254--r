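Package: simpletext
Title: Text Simplification Editor Engine and Evaluation Metrics for Health Texts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Engine behind a human-in-the-loop text simplification editor for
    patient-facing health materials, together with the measurement stack used
    to evaluate simplification studies. Detects difficult words and phrases by
    corpus frequency, ranks substitution candidates by embedding-based context
    fit, matches sentence-level rewrite rules, builds lexical chains at exact,
    synonym and semantic match levels, and computes readability statistics
    (Flesch-Kincaid grade, word/sentence/noun/verb counts, average word
    frequency) with original-versus-simplified comparison reports. The
    evaluation side scores free recall against source texts (ROUGE-1/2/L,
    mean-embedding cosine similarity, similar/matching word proportions),
    filters participant responses by reading time, and runs the study analysis
    (one-way ANOVA across two text conditions, one-tailed Pearson correlations,
    Bonferroni correction). A deterministic synthetic-data generator emulates
    all lexical resources and participant responses with injectable condition
    effects, so the full pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
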