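# Text substrate: tokenization, sentence splitting, coarse POS tagging,
# syllable counting, Flesch-Kincaid grade.

# Default abbreviation list used by the sentence splitter; a trailing period
# after one of these does not end a sentence.
DEFAULT_ABBREVIATIONS <- c(
  "dr", "mr", "mrs", "ms", "prof", "sr", "jr", "st",
  "etc", "eg", "ie", "e.g", "i.e", "vs", "cf", "fig", "no", "al"
)

WORD_TOKEN_RE <- "[\\p{L}\\p{N}]+(?:['’-][\\p{L}\\p{N}]+)*"

#' Tokenize a text into a document
#'
#' Splits a UTF-8 text into tokens (Unicode word boundaries, hyphenated and
#' apostrophe forms kept as one token, each punctuation character its own
#' token), assigns coarse part-of-speech tags, and groups tokens into
#' sentences. Sentences end at terminal punctuation (`.`, `!`, `?`) followed
#' by whitespace plus an uppercase letter or by end of text; a period after a
#' known abbreviation does not end a sentence.
#'
#' @param text A length-one character string (may be empty).
#' @param abbreviations Character vector of lowercase abbreviations whose
#'   trailing period is not sentence-final.
#' @return An object of class `st_document`: a list with elements `text`
#'   (the input), `tokens` (a tibble with columns `surface`, `lemma`, `pos`,
#'   `start`, `end`, `is_word`, `sentence`; offsets are 0-based half-open so
#'   that `substr(text, start + 1, end)` is the surface), and `sentences`
#'   (a tibble with token-index columns `first` (inclusive) and `last`
#'   (exclusive) partitioning the token list).
#'
#' @examples
#' doc <- tokenize("The cat sat. The cat ran.")
#' doc$tokens$surface
#' n_words(doc)
#' @export
tokenize <- function(text, abbreviations = DEFAULT_ABBREVIATIONS) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  if (!nzchar(text)) {
    return(new_document(text,
                        tibble::tibble(surface = character(), lemma = character(),
                                       pos = character(), start = integer(),
                                       end = integer(), is_word = logical(),
                                       sentence = integer()),
                        tibble::tibble(first = integer(), last = integer())))
  }
  pat <- paste0("(", WORD_TOKEN_RE, ")|\\S")
  m <- gregexpr(pat, text, perl = TRUE)[[1]]
  if (m[1] == -1L) {
    return(tokenize(""))
  }
  starts <- as.integer(m) - 1L                      # 0-based
  lens <- attr(m, "match.length")
  surfaces <- substring(text, starts + 1L, starts + lens)
  is_word <- grepl("\\p{L}", surfaces, perl = TRUE)
  is_punct <- !grepl("[\\p{L}\\p{N}]", surfaces, perl = TRUE)

  pos <- tag_pos(surfaces, is_word, is_punct)
  lemma <- mapply(lemmatize, tolower(surfaces), pos, USE.NAMES = FALSE)

  tokens <- tibble::tibble(
    surface = surfaces, lemma = lemma, pos = pos,
    start = starts, end = starts + lens,
    is_word = is_word, sentence = NA_integer_
  )
  sentences <- split_sentences(text, tokens, abbreviations)
  for (i in seq_len(nrow(sentences))) {
    idx <- seq.int(sentences$first[i] + 1L, sentences$last[i])
    tokens$sentence[idx] <- i
  }
  new_document(text, tokens, sentences)
}

new_document <- function(text, tokens, sentences) {
  structure(list(text = text, tokens = tokens, sentences = sentences),
            class = "st_document")
}

#' @export
print.st_document <- function(x, ...) {
  cat(sprintf("<st_document> %d chars, %d tokens (%d words), %d sentences\n",
              nchar(x$text), nrow(x$tokens), sum(x$tokens$is_word),
              nrow(x$sentences)))
  invisible(x)
}

#' Word and sentence counts of a document
#'
#' @param doc An `st_document`.
#' @return Integer count.
#' @export
n_words <- function(doc) sum(doc$tokens$is_word)

#' @rdname n_words
#' @export
n_sentences <- function(doc) nrow(doc$sentences)

# Sentence boundaries: a token in {. ! ?} ends the current sentence when it is
# followed by end-of-text or whitespace + uppercase, and (for ".") the
# preceding word token is not a listed abbreviation. Spans are token-index
# ranges [first, last) over ALL tokens and partition the token list.
split_sentences <- function(text, tokens, abbreviations) {
  n <- nrow(tokens)
  boundaries <- integer(0)
  last_word <- NA_character_
  for (i in seq_len(n)) {
    surf <- tokens$surface[i]
    if (tokens$is_word[i]) last_word <- tolower(surf)
    if (surf %in% c(".", "!", "?")) {
      if (surf == "." && !is.na(last_word) && last_word %in% abbreviations) next
      after <- tokens$end[i]
      rest <- substring(text, after + 1L)
      if (!nzchar(trimws(rest)) ||
          grepl("^\\s+[\"'“‘(]*\\p{Lu}", rest, perl = TRUE)) {
        boundaries <- c(boundaries, i)
      }
    }
  }
  # boundary token i closes span (prev, i]; trailing tokens form a final span
  firsts <- c(0L, boundaries)
  lasts <- c(boundaries, n)
  keep <- firsts < lasts
  tibble::tibble(first = firsts[keep], last = lasts[keep])
}

# ---- coarse POS tagging ----------------------------------------------------
# Deterministic rule/lexicon tagger onto the 6-tag set
# {NOUN, VERB, ADJ, ADV, OTHER, PUNCT}. Closed-class words first, then
# suffix heuristics; remaining content words default to NOUN.

POS_CLOSED <- local({
  det <- c("the", "a", "an", "this", "that", "these", "those", "some", "any",
           "each", "every", "no", "all", "both", "either", "neither", "such")
  pron <- c("i", "you", "he", "she", "it", "we", "they", "me", "him", "her",
            "us", "them", "my", "your", "his", "its", "our", "their", "mine",
            "yours", "hers", "ours", "theirs", "myself", "yourself", "himself",
            "herself", "itself", "ourselves", "themselves", "who", "whom",
            "whose", "which", "what", "someone", "anyone", "everyone", "nobody",
            "something", "anything", "everything", "nothing", "one", "oneself")
  prep <- c("of", "in", "on", "at", "by", "for", "with", "about", "against",
            "between", "into", "through", "during", "before", "after", "above",
            "below", "to", "from", "up", "down", "out", "off", "over", "under",
            "within", "without", "among", "across", "toward", "towards", "upon",
            "per", "than", "via", "near", "along", "around", "behind", "beyond",
            "despite", "except", "inside", "outside", "since", "until", "unless")
  conj <- c("and", "or", "but", "nor", "so", "yet", "if", "while", "because",
            "although", "though", "whereas", "whether", "when", "where", "as",
            "that", "once", "how", "why")
  misc <- c("not", "n't", "there", "here", "also", "too", "then", "thus",
            "however", "therefore", "moreover", "instead", "rather", "quite",
            "very", "just", "even", "only", "again", "still", "yes")
  unique(c(det, pron, prep, conj, misc))
})

POS_VERBS <- c(
  "be", "is", "are", "am", "was", "were", "been", "being",
  "have", "has", "had", "having", "do", "does", "did", "doing", "done",
  "can", "could", "will", "would", "shall", "should", "may", "might", "must",
  "get", "gets", "got", "gotten", "getting", "make", "makes", "made", "making",
  "take", "takes", "took", "taken", "go", "goes", "went", "gone",
  "come", "comes", "came", "see", "sees", "saw", "seen", "know", "knows",
  "knew", "known", "give", "gives", "gave", "given", "find", "finds", "found",
  "think", "thinks", "thought", "say", "says", "said", "tell", "tells", "told",
  "become", "becomes", "became", "keep", "keeps", "kept", "let", "lets",
  "begin", "begins", "began", "begun", "show", "shows", "showed", "shown",
  "need", "needs", "needed", "feel", "feels", "felt", "seem", "seems",
  "occur", "occurs", "occurred", "include", "includes", "included", "includes",
  "cause", "causes", "caused", "lead", "leads", "led", "affect", "affects",
  "help", "helps", "helped", "reduce", "reduces", "reduced", "develop",
  "develops", "developed", "prevent", "prevents", "treat", "treats", "treated",
  "use", "uses", "used", "using"
)

POS_ADJ <- c(
  "good", "bad", "high", "low", "long", "short", "large", "small", "big",
  "new", "old", "young", "severe", "mild", "chronic", "acute", "common",
  "rare", "difficult", "easy", "simple", "complex", "hard", "important",
  "serious", "normal", "abnormal", "early", "late", "first", "second",
  "third", "last", "next", "other", "same", "different", "main", "major",
  "minor", "many", "few", "several", "more", "most", "less", "least",
  "much", "own", "certain", "possible", "likely", "medical", "healthy", "sick"
)

POS_ADV <- c("often", "never", "always", "sometimes", "usually", "well",
             "now", "soon", "later", "already", "almost", "perhaps", "away")

ADV_LY_EXCEPTIONS <- c("family", "supply", "reply", "apply", "italy", "july",
                       "assembly", "monopoly", "anomaly", "belly", "jelly",
                       "fly", "butterfly", "ally", "rally", "bully", "folly",
                       "jolly", "holy", "early", "only")

tag_pos <- function(surfaces, is_word, is_punct) {
  lw <- tolower(surfaces)
  n <- length(surfaces)
  pos <- character(n)
  prev_word <- ""
  determiners <- c("the", "a", "an", "this", "that", "these", "those",
                   "its", "his", "her", "their", "our", "your", "my")
  for (i in seq_len(n)) {
    w <- lw[i]
    tag <- if (is_punct[i]) {
      "PUNCT"
    } else if (!is_word[i]) {
      "OTHER"                                    # numerals and similar
    } else if (w %in% POS_CLOSED) {
      "OTHER"
    } else if (w %in% POS_VERBS) {
      if (prev_word %in% determiners) "NOUN" else "VERB"
    } else if (w %in% POS_ADV ||
               (endsWith(w, "ly") && nchar(w) > 4 &&
                !w %in% ADV_LY_EXCEPTIONS)) {
      "ADV"
    } else if (w %in% POS_ADJ) {
      "ADJ"
    } else if (grepl("(ize|ise|ify)(s|d)?$|izing$|ising$|ifying$", w)) {
      "VERB"
    } else if (grepl("(ous|ful|less|ive|able|ible|ic|ical|al)$", w) &&
               nchar(w) > 4) {
      "ADJ"
    } else if (grepl("(ing|ed|en)$", w) && nchar(w) > 4) {
      # participles read as verbal unless in a clearly nominal slot
      if (prev_word %in% determiners) "NOUN" else "VERB"
    } else {
      "NOUN"
    }
    pos[i] <- tag
    if (is_word[i]) prev_word <- w
  }
  pos
}

# Light lemmatizer: lowercasing plus plural stripping for nouns. Enough for
# exact-match lexical chaining; not a full morphological analyzer.
lemmatize <- function(lw, pos) {
  if (pos != "NOUN" || nchar(lw) < 4) return(lw)
  if (grepl("ies$", lw)) return(sub("ies$", "y", lw))
  if (grepl("(ses|xes|zes|ches|shes)$", lw)) return(sub("es$", "", lw))
  if (grepl("[^su]s$", lw) && !grepl("ss$", lw)) return(sub("s$", "", lw))
  lw
}

# ---- syllables and readability ----------------------------------------------

#' Count syllables in a word
#'
#' Vowel-group heuristic: the count is the number of maximal runs of
#' `aeiouy`; a silent final "e" is dropped unless it is the word's only
#' vowel group; the result is never below 1. An exception dictionary can
#' override the heuristic for listed words.
#'
#' @param word A non-empty alphabetic string.
#' @param exceptions Optional named integer vector of overrides,
#'   e.g. `c(people = 2)` (names matched lowercase).
#' @return A positive integer.
#' @examples
#' count_syllables("asthma")     # 2
#' count_syllables("cirrhosis")  # 3
#' @export
count_syllables <- function(word, exceptions = NULL) {
  stopifnot(is.character(word), length(word) == 1L)
  if (!grepl("^\\p{L}+$", word, perl = TRUE)) {
    stop("count_syllables() requires a non-empty alphabetic word, got: ",
         dQuote(word))
  }
  lw <- tolower(word)
  if (!is.null(exceptions) && lw %in% names(exceptions)) {
    return(as.integer(exceptions[[lw]]))
  }
  runs <- gregexpr("[aeiouy]+", lw)[[1]]
  if (runs[1] == -1L) return(1L)
  n <- length(runs)
  last_start <- runs[n]
  last_len <- attr(runs, "match.length")[n]
  # silent final e: a final run that is exactly the terminal "e"
  if (n > 1L && last_len == 1L && last_start == nchar(lw) &&
      substring(lw, nchar(lw)) == "e") {
    n <- n - 1L
  }
  max(1L, n)
}

# Syllables of an arbitrary token: letters only, hyphen/apostrophe parts
# counted separately and summed.
token_syllables <- function(surface, exceptions = NULL) {
  parts <- regmatches(surface, gregexpr("\\p{L}+", surface, perl = TRUE))[[1]]
  if (length(parts) == 0L) return(0L)
  sum(vapply(parts, count_syllables, integer(1), exceptions = exceptions))
}

#' Flesch-Kincaid grade level
#'
#' Computes the grade-level formula
#' `0.39 * words/sentences + 11.8 * syllables/words - 15.59`
#' over a tokenized document, using [count_syllables()] per word token.
#' The result is a U.S. school-grade estimate and may be negative for very
#' simple text.
#'
#' @param doc An `st_document` with at least one word token and one sentence.
#' @param syllable_exceptions Passed to [count_syllables()].
#' @return A single numeric grade.
#' @examples
#' flesch_kincaid(tokenize("The cat sat. The cat ran."))  # -2.62
#' @export
flesch_kincaid <- function(doc, syllable_exceptions = NULL) {
  stopifnot(inherits(doc, "st_document"))
  w <- n_words(doc)
  s <- n_sentences(doc)
  if (w < 1L || s < 1L) stop("flesch_kincaid() requires a non-empty document")
  syl <- sum(vapply(doc$tokens$surface[doc$tokens$is_word], token_syllables,
                    integer(1), exceptions = syllable_exceptions))
  0.39 * (w / s) + 11.8 * (syl / w) - 15.59
}
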