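# Engine fixtures: frequency lexicon with one rare word among common ones,
# substitutions for the rare words only.
engine_fixture <- function() {
  freq <- toy_freq(the = 10000, patients = 10000, take = 10000,
                   medicine = 10000, daily = 10000, utilize = 10,
                   inhalers = 8000, subsequent = 10, visits = 9000,
                   myocardial = 12, infarction = 15)
  subs <- toy_subs(
    c("utilize", "subsequent", "myocardial infarction"),
    list("use", c("later", "following", "followed by"), "heart attack"))
  list(freq = freq, subs = subs)
}

test_that("difficult-span detection flags rare lexicon phrases only", {
  fx <- engine_fixture()
  expect_equal(nrow(detect_difficult_spans(tokenize(""), fx$freq, fx$subs)),
               0L)

  doc <- tokenize("Patients utilize inhalers and subsequent visits help.")
  sp <- detect_difficult_spans(doc, fx$freq, fx$subs, 0.5)
  expect_setequal(sp$phrase, c("utilize", "subsequent"))
  # brute-force threshold check: flagged iff lexicon match AND freq below the
  # level-0.5 quantile of the count distribution
  thr <- unname(quantile(as.numeric(fx$freq), 0.5))
  expect_true(all(sp$frequency < thr))
  expect_false(any(c("patients", "inhalers") %in% sp$phrase))
  # flagged char spans point at the right text
  expect_equal(substring(doc$text, sp$char_start + 1L, sp$char_end),
               c("utilize", "subsequent"))
})

test_that("multi-token phrases longest-match and spans never overlap", {
  fx <- engine_fixture()
  doc <- tokenize("A myocardial infarction needs care.")
  sp <- detect_difficult_spans(doc, fx$freq, fx$subs, 0.5)
  expect_equal(sp$phrase, "myocardial infarction")
  expect_equal(sp$candidates[[1]], "heart attack")
  # phrase uses the minimum token frequency
  expect_equal(sp$frequency, 12)
  # overlap-freedom across many flagged spans
  doc2 <- tokenize("They utilize subsequent myocardial infarction data.")
  sp2 <- detect_difficult_spans(doc2, fx$freq, fx$subs, 1)
  expect_true(all(sp2$char_start[-1] >= head(sp2$char_end, -1)))
})

test_that("flag count is nondecreasing in the simplification level", {
  fx <- engine_fixture()
  doc <- tokenize("Patients utilize inhalers and subsequent visits help.")
  counts <- vapply(seq(0, 1, by = 0.1), function(lv) {
    nrow(detect_difficult_spans(doc, fx$freq, fx$subs, lv))
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
  expect_equal(counts[1], 0)        # level 0: threshold at the minimum count
})

test_that("candidate ranking follows context cosine with lexicon tie-breaks", {
  # candidate A collinear with the sentence context, B orthogonal
  emb <- toy_embeddings(
    c("stethoscope", "nurse", "alpha", "beta"),
    matrix(c(1, 0,
             1, 0,
             1, 0,
             0, 1), ncol = 2, byrow = TRUE))
  doc <- tokenize("The nurse used a stethoscope.")
  span <- list(token_first = 2L, token_last = 3L,   # "used"
               candidates = list(c("beta", "alpha")))
  ranked <- suggest_candidates(doc, span, emb, variety_level = 1)
  expect_equal(ranked$candidate, c("alpha", "beta"))
  expect_equal(ranked$score, c(1, 0), tolerance = 1e-12)

  # at the variety floor exactly one candidate is shown
  expect_equal(nrow(suggest_candidates(doc, span, emb, variety_level = 0)), 1L)
  # ties keep lexicon order
  tie <- suggest_candidates(doc, list(token_first = 2L, token_last = 3L,
                                      candidates = list(c("beta", "gamma"))),
                            emb, variety_level = 1)
  expect_equal(tie$candidate[1], "beta")
})

test_that("three lexicon candidates all appear at maximal variety", {
  fx <- engine_fixture()
  emb <- toy_embeddings(c("later", "following", "visits"),
                        diag(3))
  doc <- tokenize("Patients utilize inhalers and subsequent visits help.")
  sp <- detect_difficult_spans(doc, fx$freq, fx$subs, 0.5)
  sub_row <- sp[sp$phrase == "subsequent", ]
  ranked <- suggest_candidates(doc, sub_row, emb, variety_level = 1)
  expect_equal(nrow(ranked), 3L)
  # fully out-of-vocabulary candidate keeps lexicon position with NA score
  expect_true(is.na(ranked$score[ranked$candidate == "followed by"]))
})

test_that("candidate list length is nondecreasing in variety level", {
  ks <- vapply(seq(0, 1, by = 0.05), variety_k, integer(1))
  expect_true(all(diff(ks) >= 0))
  expect_true(all(ks >= 1))
  expect_equal(range(ks), c(1L, 8L))
})

test_that("sentence rules fire per sentence with fixed guidance", {
  expect_equal(nrow(match_sentence_rules(tokenize("Text."),
                                         simpletext:::new_rule_catalog(
                                           tibble::tibble(id = character(),
                                                          pattern = character(),
                                                          guidance = character(),
                                                          example = character(),
                                                          matchers = list())))),
               0L)
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    paste("nominalization", "/(tion|ment|ance|ence|ization)$/ of",
          "Replace the noun made from a verb with the verb itself.",
          "Utilization of floss helps. -> Using floss helps.", sep = "\t"),
    paste("duration", "months or years", "Rephrase vague durations.",
          "Say it plainly.", sep = "\t")), p)
  rules <- read_rule_catalog(p)
  doc <- tokenize(paste(
    "Cirrhosis damage happens over months or years.",
    "Utilization of alcohol worsens it.",
    "People use alcohol."))
  hits <- match_sentence_rules(doc, rules)
  expect_equal(nrow(hits), 2L)
  expect_setequal(hits$rule_id, c("duration", "nominalization"))
  nom <- hits[hits$rule_id == "nominalization", ]
  expect_equal(nom$sentence, 2L)                 # not the "use" sentence
  expect_equal(tolower(nom$matched), "utilization of")
  # guidance/example are the rule's fixed strings, not adapted to the text
  expect_equal(nom$guidance, rules$guidance[rules$id == "nominalization"])
  expect_equal(nom$example, rules$example[rules$id == "nominalization"])
})

test_that("edits splice text and re-tokenize consistently", {
  doc <- tokenize("The subsequent visit went well.")
  same <- apply_edit(doc, 4L, 14L, "subsequent")
  expect_identical(same$text, doc$text)

  edited <- apply_edit(doc, 4L, 14L, "followed by")
  expect_match(edited$text, "followed by", fixed = TRUE)
  expect_equal(n_words(edited), n_words(doc) + 1L)
  toks <- edited$tokens
  expect_equal(substring(edited$text, toks$start + 1L, toks$end),
               toks$surface)
  expect_error(apply_edit(doc, 10L, 5L, "x"))
})

test_that("edit sessions reject stale spans and replay exactly", {
  s <- new_edit_session("The subsequent visit went well.")
  s <- session_edit(s, 4L, 14L, "followed by")
  expect_error(session_edit(s, 0L, 3L, "A", version = 0L), "stale")
  s <- session_edit(s, 0L, 3L, "A")
  expect_equal(s$version, 2L)
  expect_identical(replay_edits(s$original_text, s$events), s$doc$text)
})

test_that("random edit sequences replay to the final text", {
  set.seed(101)
  for (trial in 1:10) {
    s <- new_edit_session("Asthma narrows the airways. Medicines relax them.")
    n_edits <- sample(1:6, 1)
    for (e in seq_len(n_edits)) {
      len <- nchar(s$doc$text)
      a <- sample.int(len + 1L, 1L) - 1L
      b <- min(len, a + sample(0:8, 1))
      repl <- paste(sample(c("", "air", "the lungs", "x", "slowly "),
                           1), collapse = "")
      s <- session_edit(s, a, b, repl)
    }
    expect_identical(replay_edits(s$original_text, s$events), s$doc$text)
    # the log round-trips through JSON lines and still replays
    p <- withr::local_tempfile(fileext = ".jsonl")
    write_edit_log(s$events, p)
    expect_identical(replay_edits(s$original_text, read_edit_log(p)),
                     s$doc$text)
  }
})

test_that("the engine is deterministic", {
  fx <- engine_fixture()
  doc <- tokenize("Patients utilize inhalers and subsequent visits help.")
  expect_identical(detect_difficult_spans(doc, fx$freq, fx$subs, 0.7),
                   detect_difficult_spans(doc, fx$freq, fx$subs, 0.7))
})
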