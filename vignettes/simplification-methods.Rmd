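---
title: "Methods: the simplification engine and the study measurement pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the simplification engine and the study measurement pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(simpletext)
```

This vignette documents the models and procedures in `simpletext`, the
assumptions behind them, the tunable parameters, and the design choices made
where the underlying editor's published description leaves the mechanism
open. Nothing here reports an empirical number that the test suite or
`scripts/acceptance.R` does not itself compute.

## The text substrate

All analyses run over a tokenized document. Tokenization uses Unicode word
boundaries, keeps hyphenated and apostrophe forms (`well-known`,
`doctor's`) as single tokens, and emits each punctuation character as its
own token with 0-based half-open character offsets, so the original string
can always be reconstructed from the tokens and their gaps. Sentences end
at `.`, `!` or `?` followed by whitespace and an uppercase letter (or end
of text); a configurable abbreviation list (`Dr.`, `e.g.`, `Fig.`, ...)
suppresses false boundaries. This is a deliberately model-free design:
clean encyclopedic prose — the kind of source material patient-education
texts are adapted from — splits reliably under these rules, and the
pipeline stays fully deterministic.

**Part-of-speech tags.** Downstream consumers need only a coarse 6-tag
vocabulary (`NOUN, VERB, ADJ, ADV, OTHER, PUNCT`): noun/verb counts for the
statistics panel and noun identification for lexical chains. The built-in
tagger is a deterministic rule/lexicon tagger: closed-class function words
map to `OTHER`; a verb lexicon (auxiliaries, modals, frequent irregulars)
and verbal suffixes (`-ize`, `-ing`, `-ed`, ...) mark verbs, with a
determiner-context override for nominal uses ("the building"); `-ly`
adverbs and common adjective suffixes fill `ADV`/`ADJ`; remaining content
words default to `NOUN`. This is intentionally biased toward nouns, which
dominate encyclopedic health text. Counts that depend on tagging
(noun/verb/chain counts) are therefore tagger-relative; word and sentence
counts are not. Lemmas are lowercased surfaces with plural stripping for
nouns — enough for exact-match chaining without a full morphological
analyzer.

**Syllables and Flesch–Kincaid.** Syllables are counted as maximal
`aeiouy` runs, dropping a silent final `e` unless it is the only vowel
group, with a floor of 1 and an optional exception dictionary (the
heuristic undercounts `-le` endings such as "people"; pass
`exceptions = c(people = 2)` where that matters). The readability score is
the grade-level formula `0.39·(W/S) + 11.8·(Syl/W) − 15.59`, chosen over
the reading-ease variant because grade levels are the scale used when
discussing patient materials (recommended writing level: grades 6–8). It
is strictly increasing in mean sentence length and in syllables per word,
and may be negative for very simple text.

## Lexical resources

Four resources drive the engine, all plain text so fixtures are diffable
and hand-editable: a frequency lexicon (`word<TAB>count`; duplicate rows
sum), embeddings in word2vec text format (`"V D"` header, then one word
and `D` floats per line; the reader validates both dimensions), a
substitution lexicon (`phrase<TAB>cand|cand|...` with an optional resource
tag, mirroring the editor's per-resource checkboxes), and a sentence-rule
catalog (`id, pattern, guidance, example`). Every reader has a writer and
write→read is the identity. In production such an editor would load a
web-scale frequency list and 300-dimensional pretrained embeddings; this
package ships neither and instead generates small deterministic stand-ins
(below), so the mechanisms — not any particular proprietary resource — are
what is reproducible.

## The engine

**Flagging.** The published description of the editor states only the
monotone *direction* of its two sliders, not their semantics. The design
adopted here: the simplification level `ℓ ∈ [0,1]` sets the difficulty
threshold to the `ℓ` quantile of the frequency lexicon's count
distribution, and a span is flagged iff it longest-matches a substitution
phrase and its frequency (minimum over tokens for multi-word phrases;
missing words count 0) is strictly below the threshold. Strict comparison
makes `ℓ = 0` flag nothing; `ℓ = 1` flags every lexicon match except
maximal-frequency ones. Leftmost-longest, non-overlapping matching is the
standard lexicon-scan convention. Flag counts are provably nondecreasing
in `ℓ` because only the threshold depends on it.

**Candidate ranking.** The production editor uses a trained
word-embedding context filter; its exact scoring is not recoverable from
the published description. The documented stand-in, isolated in one
scoring function so it can be swapped: score each candidate by
`cos(v_cand, v_ctx)` where `v_ctx` averages the embeddings of the other
in-vocabulary words in the sentence and a multi-word candidate averages
its word vectors. Ties and fully out-of-vocabulary candidates fall back to
lexicon order (the lexicon's own preference ranking); an absent score is
reported as `NA`, never invented. The variety level maps onto the
dropdown length by quartile, k ∈ {1, 3, 5, 8} — nondecreasing with a floor
of 1 so a flagged span always has at least one suggestion.

**Sentence rules.** Patterns are token-matcher sequences (literal surface,
`<POS>` tag, or `/regex/` on the lowercased surface). One suggestion per
(sentence, rule) pair, carrying the rule's fixed guidance and example —
examples are generic by design, not adapted to the text topic. The shipped
toy catalog contains a nominalization rule and a literal duration-phrase
rule.

**Edits.** Suggestions are never applied automatically (the human stays in
the loop). An edit session re-tokenizes after each splice, increments a
version counter, and refuses edits addressed to a stale version. The event
log is append-only, serializes to JSON lines, and satisfies the replay
identity `replay(original, log) = final` — tested on random edit
sequences.

## Lexical chains

Chains are built over `NOUN` tokens with greedy attachment to the most
recently updated chain containing a related member — the standard
deterministic procedure in the lexical-chain literature. Relatedness
widens across the three levels: same lemma (`EXACT`); same lemma or shared
synonym-set id (`SYNONYM`); either criterion or embedding cosine ≥ θ
(`SEMANTIC`, default θ = 0.6, valid range [−1, 1]). Only chains with ≥ 2
members are reported: a published chain count of 33 against 212 nouns in
one reference text implies singletons are not counted. Two chains *cross*
iff their position spans interleave without nesting
(`min(A) < min(B) ≤ max(A) < max(B)`); nesting and disjointness do not
count. Pairwise *relatedness* is monotone across levels (given synonym
sets containing identity and θ ≤ 1), which the suite tests directly;
chain *membership* need not be, since greedy attachment can split pairs
differently at different levels.

## Text statistics and comparison

The statistics vector contains word count, sentence count, mean sentence
length, exact-chain count, verb and noun counts, average word frequency
and Flesch–Kincaid. Average word frequency is the mean lexicon count over
in-lexicon word tokens only — out-of-lexicon words are excluded rather
than zero-counted, because a toy lexicon would otherwise drag the mean
toward 0 and make fixture tests meaningless; the in-lexicon fraction is
always reported as `freq_coverage`. Percent changes are
`(simplified − original)/original × 100`, rounded half-away-from-zero to
one decimal (matching how published comparison tables round), `NA` when
the original is 0.

## Recall metrics

All metrics preprocess identically: lowercase, punctuation stripped, no
stemming, no stopword removal (switches exposed). The participant's answer
is always the ROUGE candidate and the stimulus text the reference — the
direction that yields low recall and high unigram precision for short
answers against a long text. ROUGE-N uses clipped n-gram counts; ROUGE-L
uses the token-level LCS; `F = 2PR/(P+R)`, 0 when `P + R = 0`. An empty
answer is flagged (`empty_answer`) with zero scores rather than erroring,
so batch scoring never aborts on a blank response; a reference shorter
than `n` is a hard error. The embedding similarity is the cosine of mean
word vectors; the word proportions report exact matching and
similar-or-matching (max cosine to any text word ≥ τ, default τ = 0.5 —
the threshold is a free parameter, so similarity proportions should be
compared only within one τ). `prop_similar ≥ prop_matching` holds by
construction. The implementation is cross-checked against an independent
in-test oracle (position-marking overlap; memoized-recursion LCS) at 1e−9
on random pairs.

## The study pipeline

**Filtering.** A participant-by-text record is excluded iff its reading
time is strictly below 60 s — at exactly 60 s it is retained, reading
"< 1 min" literally. Exclusion is per text, never per participant, and a
record with missing timing is retained with a flag instead of silently
dropped.

**ANOVA.** One-way between/within decomposition with
`F = MS_between/MS_within` and the p-value from the F distribution's upper
tail (R's `pf`, i.e. the regularized incomplete beta function). With zero
within-group variance, F is defined as 0 when the means agree (p = 1) and
diverges (reported `Inf`, p = 0) otherwise. On two groups F equals the
squared pooled-variance t statistic, which the acceptance checks verify at
1e−9 against `t.test`. One caveat is inherited from the emulated design:
the four readings per participant enter the one-way ANOVA as independent
observations (no repeated-measures term), exactly as the published
analysis specifies; a mixed model is out of scope.

**Correlations.** One-tailed Pearson (positive alternative),
`t = r√((n−2)/(1−r²))` on `n − 2` df. The secondary analysis correlates
per-participant mean question accuracy with education level (ordinal 1–6,
from no-high-school to doctorate) and language-at-home level (ordinal 1–5,
never-English to only-English); with four post hoc tests the
Bonferroni-corrected level is 0.05/4 = 0.0125. "Question accuracy"
averages the items answered with and after reading — the two while-reading
multiple-choice items, the five repeated true/false items and the four
after-reading multiple-choice items — excluding the five before-reading
items; the published phrasing is ambiguous about the repeated true/false
items, and including them is the reading adopted here (a `mc_only` switch
provides the narrower set).

**Report.** One row per measure (Likert; 16 question items; recall and
expert measures; nine ROUGE columns), with condition-wise mean (SD), F and
p. Binary items are reported on the percent scale. Empty condition cells
and non-estimable ANOVAs are flagged, never fabricated.

## The synthetic generator

The generator emulates the *statistical structure* of the study, not its
language: 49 participants × 4 texts, each participant reading 2 originals
and 2 simplified texts under 6 counterbalanced combinations (the ways of
choosing which 2 of 4 texts are original), with ~21% (41/196) of readings
faster than the 60 s cutoff. Perceived difficulty is a latent normal per
condition discretized to the 1–4 Likert scale (defaults: mean 2.28
SD 0.697 original, 2.55/0.681 simplified); each question item is Bernoulli
with per-condition accuracy; recall metrics and expert scores are clamped
normals — all defaults taken from the emulated study's printed condition
means and SDs. Demographics follow the published sample's education and
language distributions. `null_effects = TRUE` copies the ORIGINAL
parameters onto SIMPLIFIED, giving the null configuration under which the
pipeline's measure-level type-I error is estimated (nominal 0.05); with
effects on, `expected_likert_means()` provides the closed-form discretized
means against which recovery bias is measured. Everything derives from one
seed and is byte-identical across runs.

What passing tests on this generator do **not** show: real free-recall
answers are text, not draws from a normal — the generator emulates the
distribution of metric *values*, so it validates the analysis pipeline,
not the linguistic behavior of the metrics on human answers (the metric
implementations are validated separately on token fixtures). Likewise the
toy embedding geometry (synonym clusters on orthogonal coordinates) makes
context ranking exactly analyzable but is far cleaner than any trained
embedding space.

## Numerical and scale choices

Problem sizes used by the checks: 100 random datasets for the ANOVA/t²
identity, 200 generator seeds for the type-I rate (pooled over all report
measures; ~6 800 tests), 60 seeds for effect recovery (Monte-Carlo SE of
the mean difference ≈ 0.015, tolerance 0.05), 100 random token pairs for
the ROUGE oracle, 25 random edit sequences for replay, 11 slider settings
for monotonicity. These sizes keep the whole suite under a minute of
simulation while leaving each check's Monte-Carlo error well inside its
tolerance. Quantiles use R's default (type 7) definition; any continuous
quantile type preserves slider monotonicity.

## Known limitations

- The rule tagger is a heuristic; tag-dependent counts (noun, verb, chain)
  should be compared only within a single tagger, and no claim is made
  that they reproduce counts produced by trained taggers.
- The syllable heuristic undercounts some `-le` words; Flesch–Kincaid
  values are comparable within the package, not across syllabifiers.
- The context filter is a documented stand-in for the editor's trained
  filterer and is deliberately isolated behind `suggest_candidates()`.
- The chain algorithm's greedy attachment is one standard choice; chain
  counts published for the original editor are not reproduced exactly
  because its precise algorithm (and whether singletons count) is
  unstated.
- English only; no dependency parsing or coreference.
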