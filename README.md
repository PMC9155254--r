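# simpletext

Health information is routinely written above the 6th–8th grade reading
level that plain-language guidelines recommend, and readability formulas
alone neither guide a writer toward concrete fixes nor predict whether
readers actually understand the result. `simpletext` implements the engine
behind a human-in-the-loop simplification editor for patient-facing health
text, together with the full measurement stack needed to evaluate such an
editor in a two-condition reading study (original vs. simplified texts). It
is aimed at health-communication researchers and NLP practitioners who want
a reproducible, scriptable version of both the editing aids and the study
analysis.

## What it computes

**Editor engine**

- *Difficult-span detection.* A span is flagged iff it matches a phrase in a
  substitution lexicon (leftmost-longest, non-overlapping) **and** its corpus
  frequency `f(w)` falls below a threshold `q_level`, the `level` quantile of
  the frequency lexicon's count distribution. The "simplification level"
  slider is this quantile, so the number of flags is monotone in it.
- *Context-ranked candidates.* Each substitution candidate `c` is scored by
  cosine similarity `cos(v_c, v_ctx)` between its (mean) word embedding and
  the mean embedding of the other words in the sentence; the "variety level"
  slider truncates the ranked list to k ∈ {1, 3, 5, 8}.
- *Sentence-level rules.* A small pattern language over lowercased surfaces,
  POS tags and regexes (e.g. a nominalization rule `/(tion|ment|...)$/ of`)
  attaches fixed guidance and an example to matching sentences.
- *Lexical chains.* Nouns are greedily chained to the most recently updated
  related chain, at three widening levels: exact lemma, shared synonym set,
  embedding cosine ≥ θ. Crossing chains (spans that interleave without
  nesting) indicate less cohesive text.
- *Readability statistics.* Word/sentence/noun/verb counts, average corpus
  word frequency, and the Flesch–Kincaid grade
  `0.39·(W/S) + 11.8·(Syl/W) − 15.59`, plus an original-vs-simplified
  percent-change report.
- *Edit log.* Every edit is an event; replaying the log over the original
  text reproduces the final text exactly.

**Evaluation stack**

- ROUGE-1/2/L precision, recall and F (`F = 2PR/(P+R)`), with the
  participant's recall as candidate and the stimulus text as reference.
- Mean-embedding cosine similarity and the proportions of answer words
  matching / semantically similar to the text.
- Response filtering (a reading excluded iff < 60 s was spent), one-way
  ANOVA across the two conditions (`F = MS_between/MS_within`), one-tailed
  Pearson correlations, and the Bonferroni threshold `α/m`.
- A deterministic synthetic generator for all resources and for participant
  responses (49 participants × 4 texts, 6 counterbalanced combinations) with
  injectable condition effects, used for type-I-error and
  parameter-recovery checks.

## Worked example

```r
library(simpletext)

paths <- make_resources("demo-resources", seed = 1)   # toy lexicons/embeddings
freq  <- read_frequency_list(paths$frequency)
subs  <- read_substitution_lexicon(paths$substitutions)
emb   <- read_embeddings(paths$embeddings)
rules <- read_rule_catalog(paths$rules)

text <- paste("Patients utilize inhalers, and subsequent visits to a",
              "physician help. Damage develops over months or years.")
doc <- tokenize(text)

detect_difficult_spans(doc, freq, subs, simplification_level = 0.5)
#>   phrase     char_start char_end frequency
#> 1 utilize             9       16        10
#> 2 subsequent         31       41        10
#> 3 physician           54       63       10
```

Each flagged phrase is rare (count 10 vs. 10 000 for common words) and has
lexicon candidates. Ranking the candidates for "subsequent" in context:

```r
suggest_candidates(doc, spans[spans$phrase == "subsequent", ], emb,
                   variety_level = 1)
#>   candidate     score  rank
#> 1 later       -0.0702     1
#> 2 following   -0.101      2
#> 3 followed by NA          3
```

All three lexicon candidates appear at maximal variety; "followed by" has no
embedding in the toy table, so its score is absent and it keeps its lexicon
position. The sentence rule for vague durations fires on the second
sentence ("months or years"), and `flesch_kincaid(doc)` returns 9.66 for
this two-sentence text. Applying the first suggestion through an edit
session:

```r
s <- new_edit_session(text)
sp <- detect_difficult_spans(s$doc, freq, subs, 0.5)
s <- session_edit(s, sp$char_start[1], sp$char_end[1], "use")
s$doc$text
#> "Patients use inhalers, and subsequent visits to a physician help. ..."
replay_edits(s$original_text, s$events) == s$doc$text   # TRUE, always
```

The study side, on synthetic responses (seed 1):

```r
resp <- make_responses(synthetic_config(seed = 1))   # 196 rows = 49 x 4
kept <- filter_responses(resp)                       # 153 retained, 43 too fast
report <- build_report(kept$retained)
report[report$column %in% c("likert", "tf_after_5"), ]
#>   measure              mean_original mean_simplified     F       p
#> 1 4-point Likert scale          2.30            2.39  0.70 0.405
#> 2 TF5 (after)                  49.37           74.32 10.61 0.00139
```

Binary items are on the percent scale: under the default (study-condition)
effects, the fifth true/false question improves from ~49% to ~74% accuracy
with simplification and the ANOVA flags it, while this seed's Likert
difference does not reach significance — single-seed noise the acceptance
script averages away.

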