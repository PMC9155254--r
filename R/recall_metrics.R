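# Scoring free recall against a source text: ROUGE-1/2/L precision, recall
# and F, mean-embedding cosine similarity, and the proportions of answer
# words that match or are semantically similar to the text. The answer is
# always the candidate and the stimulus text the reference, so short answers
# against a long text give low recall and comparatively high precision.

#' Tokenize text for recall metrics
#'
#' Default preprocessing for every recall metric: lowercase word tokens with
#' punctuation stripped; no stemming, no stopword removal. Both switches are
#' exposed for sensitivity analyses.
#'
#' @param text A string, or an already-tokenized character vector (returned
#'   unchanged apart from lowercasing).
#' @param lowercase,strip_punct Logical switches.
#' @return Character vector of tokens.
#' @export
recall_tokens <- function(text, lowercase = TRUE, strip_punct = TRUE) {
  if (length(text) != 1L) {
    toks <- as.character(text)
  } else {
    doc <- tokenize(text)
    toks <- doc$tokens$surface[if (strip_punct) doc$tokens$is_word
                               else rep(TRUE, nrow(doc$tokens))]
  }
  if (lowercase) toks <- tolower(toks)
  toks
}

new_rouge <- function(precision, recall, variant, flag = NA_character_) {
  f <- if ((precision + recall) > 0) {
    2 * precision * recall / (precision + recall)
  } else {
    0
  }
  structure(list(precision = precision, recall = recall, f_measure = f,
                 variant = variant, flag = flag),
            class = "st_rouge")
}

#' @export
print.st_rouge <- function(x, ...) {
  cat(sprintf("ROUGE %s  P=%.4f R=%.4f F=%.4f\n",
              x$variant, x$precision, x$recall, x$f_measure))
  invisible(x)
}

#' ROUGE-N overlap score
#'
#' Clipped n-gram overlap between an answer and a reference:
#' recall = overlap / reference n-grams, precision = overlap / answer
#' n-grams, F = harmonic mean (0 when P + R = 0). "Clipped" means each
#' distinct n-gram contributes at most the minimum of its two counts.
#'
#' @param answer,reference Token vectors (see [recall_tokens()]) or strings.
#' @param n N-gram order, 1 or 2.
#' @return An `st_rouge` with `variant` `"UNIGRAM"` or `"BIGRAM"`.
#' @examples
#' rouge_n("the cat sat", "the cat ran fast", 1)  # P=2/3 R=1/2 F=4/7
#' @export
rouge_n <- function(answer, reference, n = 1L) {
  stopifnot(n %in% c(1L, 2L))
  a <- recall_tokens(answer)
  r <- recall_tokens(reference)
  if (length(r) < n) {
    stop("reference has ", length(r), " tokens, fewer than n = ", n)
  }
  ang <- ngrams(a, n)
  rng <- ngrams(r, n)
  overlap <- clipped_overlap(ang, rng)
  precision <- if (length(ang)) overlap / length(ang) else 0
  recall <- overlap / length(rng)
  new_rouge(precision, recall,
            variant = if (n == 1L) "UNIGRAM" else "BIGRAM")
}

ngrams <- function(tokens, n) {
  if (length(tokens) < n) return(character(0))
  if (n == 1L) return(tokens)
  vapply(seq_len(length(tokens) - n + 1L), function(i) {
    paste(tokens[i:(i + n - 1L)], collapse = " ")
  }, character(1))
}

clipped_overlap <- function(a, b) {
  if (!length(a) || !length(b)) return(0)
  ta <- table(a); tb <- table(b)
  shared <- intersect(names(ta), names(tb))
  sum(pmin(as.numeric(ta[shared]), as.numeric(tb[shared])))
}

#' ROUGE-L (longest common subsequence) score
#'
#' LCS length between the flat token sequences; precision = LCS / answer
#' length, recall = LCS / reference length, F harmonic. An empty answer
#' yields precision 0 with `flag = "empty_answer"` rather than an error.
#'
#' @inheritParams rouge_n
#' @return An `st_rouge` with `variant` `"LCS"`.
#' @export
rouge_l <- function(answer, reference) {
  a <- recall_tokens(answer)
  r <- recall_tokens(reference)
  if (length(r) < 1L) stop("reference is empty")
  if (length(a) == 0L) return(new_rouge(0, 0, "LCS", flag = "empty_answer"))
  l <- lcs_length(a, r)
  new_rouge(l / length(a), l / length(r), "LCS")
}

# Standard O(mn) dynamic program, rolling rows.
lcs_length <- function(a, b) {
  prev <- integer(length(b) + 1L)
  for (i in seq_along(a)) {
    cur <- integer(length(b) + 1L)
    for (j in seq_along(b)) {
      cur[j + 1L] <- if (a[i] == b[j]) prev[j] + 1L
                     else max(prev[j + 1L], cur[j])
    }
    prev <- cur
  }
  prev[length(b) + 1L]
}

#' Embedding cosine similarity between an answer and a text
#'
#' Cosine between the mean word vector of the answer tokens and of the text
#' tokens. Out-of-vocabulary tokens are skipped; it is an error if either
#' side has no in-vocabulary token.
#'
#' @inheritParams rouge_n
#' @param emb An `st_embedding_table`.
#' @return A number in `[-1, 1]`.
#' @export
embedding_similarity <- function(answer, text, emb) {
  av <- mean_word_vector(recall_tokens(answer), emb)
  tv <- mean_word_vector(recall_tokens(text), emb)
  if (is.null(av) || is.null(tv)) {
    stop("no in-vocabulary words on one side of embedding_similarity()")
  }
  cosine_similarity(av, tv)
}

#' Proportion of answer words similar / matching the text
#'
#' `prop_matching` is the fraction of answer word tokens whose lowercased
#' form occurs in the text. `prop_similar` additionally admits words whose
#' maximum embedding cosine to any text word is at least `tau`, so
#' `prop_similar >= prop_matching` always.
#'
#' @inheritParams embedding_similarity
#' @param tau Cosine threshold for "similar", default 0.5.
#' @return Named list `prop_similar`, `prop_matching`, both in `[0, 1]`.
#' @export
word_match_proportions <- function(answer, text, emb = NULL, tau = 0.5) {
  a <- recall_tokens(answer)
  t <- recall_tokens(text)
  stopifnot(length(a) >= 1L)
  text_set <- unique(t)
  matching <- a %in% text_set
  similar <- matching
  if (!is.null(emb)) {
    tvecs <- lapply(text_set, embedding_vector, emb = emb)
    tmat <- do.call(rbind, Filter(Negate(is.null), tvecs))
    if (!is.null(tmat)) {
      for (i in which(!matching)) {
        av <- embedding_vector(emb, a[i])
        if (is.null(av)) next
        sims <- apply(tmat, 1L, cosine_similarity, b = av)
        if (any(!is.na(sims) & sims >= tau)) similar[i] <- TRUE
      }
    }
  }
  list(prop_similar = mean(similar), prop_matching = mean(matching))
}

#' Validate an expert free-recall score
#'
#' Schema holder for the double-blind expert evaluation: number of correct
#' facts, whether the main point was conveyed, and two 0-4 scales —
#' correctness (4 no errors ... 0 all wrong) and completeness (4 complete
#' ... 0 nothing).
#'
#' @param correct_facts Nonnegative integer.
#' @param main_point Logical.
#' @param correctness,completeness Integers in 0..4.
#' @return A validated list of class `st_expert_score`.
#' @export
expert_score <- function(correct_facts, main_point, correctness, completeness) {
  stopifnot(length(correct_facts) == 1L, correct_facts >= 0,
            correct_facts == as.integer(correct_facts),
            is.logical(main_point), length(main_point) == 1L,
            correctness %in% 0:4, completeness %in% 0:4)
  structure(list(correct_facts = as.integer(correct_facts),
                 main_point = main_point,
                 correctness = as.integer(correctness),
                 completeness = as.integer(completeness)),
            class = "st_expert_score")
}

#' Score a table of recall answers against their source texts
#'
#' Convenience wrapper producing one metric row per answer: unique word
#' count, cosine similarity, similar/matching proportions and the three
#' ROUGE variants.
#'
#' @param answers A data frame with columns `participant_id`, `text_id`,
#'   `condition`, `answer`.
#' @param texts Named character vector of source texts, names = text ids.
#' @param emb An `st_embedding_table` (or `NULL` to skip embedding metrics).
#' @param tau Threshold for [word_match_proportions()].
#' @return A tibble with one row per answer.
#' @export
score_recall_answers <- function(answers, texts, emb = NULL, tau = 0.5) {
  rows <- lapply(seq_len(nrow(answers)), function(i) {
    ans <- answers$answer[i]
    ref <- texts[[answers$text_id[i]]]
    atoks <- recall_tokens(ans)
    r1 <- rouge_n(atoks, ref, 1L)
    r2 <- if (length(recall_tokens(ref)) >= 2L) rouge_n(atoks, ref, 2L)
          else new_rouge(0, 0, "BIGRAM", flag = "short_reference")
    rl <- rouge_l(atoks, ref)
    props <- if (length(atoks)) word_match_proportions(atoks, ref, emb, tau)
             else list(prop_similar = NA_real_, prop_matching = NA_real_)
    cosim <- if (!is.null(emb)) {
      tryCatch(embedding_similarity(atoks, ref, emb),
               error = function(e) NA_real_)
    } else NA_real_
    tibble::tibble(
      participant_id = answers$participant_id[i],
      text_id = answers$text_id[i],
      condition = answers$condition[i],
      unique_word_count = length(unique(atoks)),
      cosine_similarity = cosim,
      prop_similar = props$prop_similar,
      prop_matching = props$prop_matching,
      rouge_1_precision = r1$precision, rouge_1_recall = r1$recall,
      rouge_1_f = r1$f_measure,
      rouge_2_precision = r2$precision, rouge_2_recall = r2$recall,
      rouge_2_f = r2$f_measure,
      rouge_l_precision = rl$precision, rouge_l_recall = rl$recall,
      rouge_l_f = rl$f_measure
    )
  })
  do.call(rbind, rows)
}
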