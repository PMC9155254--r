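# The "Statistics" tab: a per-text measurement vector and the
# original-versus-simplified comparison report with percent changes.

#' Compute the text-statistics vector
#'
#' Word count, sentence count, mean sentence length (words per sentence),
#' exact lexical-chain count, verb and noun counts, average corpus word
#' frequency, and Flesch-Kincaid grade. Average word frequency is the mean
#' lexicon count over the word tokens found in the lexicon;
#' out-of-lexicon tokens are excluded (not zero-counted) and the in-lexicon
#' fraction is reported as `freq_coverage`. With no in-lexicon token the
#' average is `NA` and coverage 0.
#'
#' @param doc A non-empty `st_document`.
#' @param freq An `st_frequency_lexicon`, or `NULL` to skip frequency fields.
#' @param chains Optional precomputed `st_chains`; defaults to EXACT chains
#'   of `doc`.
#' @return An `st_text_stats`: a one-row tibble with columns `word_count`,
#'   `sentence_count`, `mean_sentence_length`, `exact_chain_count`,
#'   `verb_count`, `noun_count`, `avg_word_frequency`, `freq_coverage`,
#'   `flesch_kincaid`.
#' @examples
#' doc <- tokenize("Asthma narrows the airways. Medicines relax the airways.")
#' compute_stats(doc)
#' @export
compute_stats <- function(doc, freq = NULL, chains = NULL) {
  stopifnot(inherits(doc, "st_document"))
  if (n_words(doc) == 0L) stop("compute_stats() requires a non-empty document")
  if (is.null(chains)) chains <- build_chains(doc, "EXACT")
  toks <- doc$tokens
  words <- tolower(toks$surface[toks$is_word])
  if (is.null(freq) || length(freq) == 0L) {
    avg_freq <- NA_real_
    coverage <- 0
  } else {
    counts <- word_frequency(freq, words, default = NA_real_)
    coverage <- mean(!is.na(counts))
    avg_freq <- if (any(!is.na(counts))) mean(counts, na.rm = TRUE) else NA_real_
  }
  out <- tibble::tibble(
    word_count = n_words(doc),
    sentence_count = n_sentences(doc),
    mean_sentence_length = n_words(doc) / n_sentences(doc),
    exact_chain_count = nrow(chains),
    verb_count = sum(toks$pos == "VERB"),
    noun_count = sum(toks$pos == "NOUN"),
    avg_word_frequency = avg_freq,
    freq_coverage = coverage,
    flesch_kincaid = flesch_kincaid(doc)
  )
  structure(out, class = c("st_text_stats", class(out)))
}

#' Original-versus-simplified comparison report
#'
#' Percent change per statistic, `(simplified - original) / original * 100`,
#' rounded half-away-from-zero to one decimal; absent (`NA`) when the
#' original value is 0 or missing. `freq_coverage` is carried along but not
#' given a percent change (it describes the lexicon, not the text).
#'
#' @param original,simplified `st_text_stats` rows computed with the same
#'   resources.
#' @return A tibble with columns `statistic`, `original`, `simplified`,
#'   `pct_change`.
#' @export
compare_stats <- function(original, simplified) {
  fields <- c("word_count", "sentence_count", "mean_sentence_length",
              "exact_chain_count", "verb_count", "noun_count",
              "avg_word_frequency", "flesch_kincaid")
  o <- as.numeric(original[1, fields])
  s <- as.numeric(simplified[1, fields])
  tibble::tibble(
    statistic = fields,
    original = o,
    simplified = s,
    pct_change = percent_change(o, s)
  )
}

#' Percent change, Table-style rounding
#'
#' @param original,simplified Numeric vectors.
#' @return `(simplified - original) / original * 100` rounded
#'   half-away-from-zero to 1 decimal; `NA` where the original is 0 or `NA`.
#' @examples
#' percent_change(481, 517)  # 7.5
#' percent_change(11, 9)     # -18.2
#' @export
percent_change <- function(original, simplified) {
  out <- ifelse(is.na(original) | is.na(simplified) | original == 0,
                NA_real_,
                round_half_away((simplified - original) / original * 100, 1L))
  as.numeric(out)
}

# round() in R is half-to-even; printed tables round half away from zero.
round_half_away <- function(x, digits = 0L) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + sqrt(.Machine$double.eps)) / m
}
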