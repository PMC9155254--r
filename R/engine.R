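# Editor core: flag difficult spans, rank substitution candidates by context
# fit, match sentence-level rewrite rules, apply edits, keep a replayable
# event log. Everything is deterministic: same document + resources + slider
# settings always yield the same suggestions.

#' Detect difficult word/phrase spans
#'
#' A span is flagged iff (a) it is a longest match of a phrase in the
#' substitution lexicon (leftmost-longest, flagged spans never overlap) and
#' (b) its corpus frequency is below the threshold set by the simplification
#' level. The threshold is the `simplification_level` quantile of the
#' frequency lexicon's count distribution, so the number of flagged spans is
#' nondecreasing in the level: at 0 (almost) nothing is flagged, at 1
#' everything with a substitution candidate is. A multi-token phrase uses the
#' minimum frequency of its tokens; words missing from the frequency lexicon
#' count as frequency 0 (maximally difficult).
#'
#' @param doc An `st_document`.
#' @param freq An `st_frequency_lexicon`.
#' @param subs An `st_substitution_lexicon`.
#' @param simplification_level Number in `[0, 1]`; the editor's
#'   "simplification level" slider.
#' @param enabled_resources `NULL` (all) or resource tags to use.
#' @return A tibble of WORD suggestions: columns `kind`, `token_first`,
#'   `token_last` (token-index half-open range), `char_start`, `char_end`
#'   (0-based half-open), `phrase`, `frequency`, `candidates` (list column,
#'   in lexicon order, unranked), `resource`.
#' @export
detect_difficult_spans <- function(doc, freq, subs, simplification_level = 0.5,
                                   enabled_resources = NULL) {
  stopifnot(inherits(doc, "st_document"),
            simplification_level >= 0, simplification_level <= 1)
  empty <- tibble::tibble(kind = character(), token_first = integer(),
                          token_last = integer(), char_start = integer(),
                          char_end = integer(), phrase = character(),
                          frequency = numeric(), candidates = list(),
                          resource = character())
  if (!is.null(enabled_resources)) {
    subs <- combine_substitution_lexicons(subs, enabled = enabled_resources)
  }
  if (nrow(doc$tokens) == 0L || nrow(subs) == 0L) return(empty)

  threshold <- if (length(freq)) {
    unname(stats::quantile(unclass(freq), simplification_level, names = FALSE))
  } else {
    Inf
  }

  phrase_tokens <- strsplit(subs$phrase, "\\s+")
  max_len <- max(vapply(phrase_tokens, length, integer(1)))
  # phrase -> first lexicon row (first occurrence wins among duplicates)
  lookup <- new.env(parent = emptyenv())
  for (i in rev(seq_len(nrow(subs)))) assign(subs$phrase[i], i, envir = lookup)

  toks <- doc$tokens
  lower <- tolower(toks$surface)
  word_idx <- which(toks$is_word)
  out <- list()
  i <- 1L
  while (i <= length(word_idx)) {
    hit <- NULL
    for (len in rev(seq_len(min(max_len, length(word_idx) - i + 1L)))) {
      span <- word_idx[i:(i + len - 1L)]
      # phrase tokens must be adjacent words (same sentence, no punct between)
      if (len > 1L && any(diff(span) != 1L)) next
      key <- paste(lower[span], collapse = " ")
      row <- get0(key, envir = lookup, ifnotfound = NULL)
      if (!is.null(row)) {
        hit <- list(row = row, span = span, len = len)
        break
      }
    }
    if (!is.null(hit)) {
      f <- min(word_frequency(freq, lower[hit$span], default = 0))
      if (f < threshold) {
        out[[length(out) + 1L]] <- tibble::tibble(
          kind = "WORD",
          token_first = hit$span[1] - 1L,       # 0-based half-open
          token_last = hit$span[hit$len],
          char_start = toks$start[hit$span[1]],
          char_end = toks$end[hit$span[hit$len]],
          phrase = subs$phrase[hit$row],
          frequency = f,
          candidates = list(subs$candidates[[hit$row]]),
          resource = subs$resource[hit$row]
        )
      }
      i <- i + hit$len
    } else {
      i <- i + 1L
    }
  }
  if (length(out) == 0L) return(empty)
  do.call(rbind, out)
}

#' Number of candidates shown at a variety level
#'
#' The editor's "variety level" slider maps onto the dropdown length by
#' quartile: below 0.25 one candidate, then 3, 5, and 8 at the top quartile.
#' Nondecreasing in the level and never below 1.
#'
#' @param variety_level Number in `[0, 1]`.
#' @return An integer `k >= 1`.
#' @export
variety_k <- function(variety_level) {
  stopifnot(variety_level >= 0, variety_level <= 1)
  if (variety_level < 0.25) 1L else if (variety_level < 0.5) 3L
  else if (variety_level < 0.75) 5L else 8L
}

#' Rank substitution candidates by context fit
#'
#' Scores each lexicon candidate for a flagged span by the cosine similarity
#' between the candidate's embedding and a context vector: the mean embedding
#' of the other word tokens in the span's sentence. A multi-word candidate is
#' represented by the mean of its word vectors. Candidates are sorted by
#' score (descending; ties and missing scores keep lexicon order) and the
#' list is truncated to [variety_k()] entries.
#'
#' @param doc An `st_document`.
#' @param span One row of [detect_difficult_spans()] output (or any list with
#'   `token_first`, `token_last`, `candidates`).
#' @param emb An `st_embedding_table`.
#' @param variety_level Number in `[0, 1]`.
#' @return A tibble with columns `candidate`, `score` (`NA` when candidate or
#'   context is fully out of vocabulary), `rank`.
#' @export
suggest_candidates <- function(doc, span, emb, variety_level = 0.5) {
  cands <- if (is.list(span$candidates) && !is.character(span$candidates)) {
    span$candidates[[1]]
  } else {
    span$candidates
  }
  stopifnot(length(cands) >= 1L)
  tok_first <- span$token_first + 1L             # back to 1-based
  tok_last <- span$token_last
  sent <- doc$tokens$sentence[tok_first]
  in_sent <- which(doc$tokens$sentence == sent & doc$tokens$is_word)
  context_idx <- setdiff(in_sent, tok_first:tok_last)
  ctx <- mean_word_vector(tolower(doc$tokens$surface[context_idx]), emb)

  scores <- vapply(cands, function(cand) {
    cv <- mean_word_vector(tolower(strsplit(cand, "\\s+")[[1]]), emb)
    if (is.null(ctx) || is.null(cv)) return(NA_real_)
    cosine_similarity(cv, ctx)
  }, numeric(1), USE.NAMES = FALSE)

  ord <- order(-ifelse(is.na(scores), -Inf, scores), seq_along(scores))
  k <- min(variety_k(variety_level), length(cands))
  keep <- ord[seq_len(k)]
  tibble::tibble(candidate = cands[keep], score = scores[keep],
                 rank = seq_len(k))
}

# Mean embedding of the in-vocabulary words; NULL when none are known.
mean_word_vector <- function(words, emb) {
  vecs <- Filter(Negate(is.null), lapply(words, embedding_vector, emb = emb))
  if (length(vecs) == 0L) return(NULL)
  colMeans(do.call(rbind, vecs))
}

#' Match sentence-level rewrite rules
#'
#' Scans every sentence for every rule pattern (see [read_rule_catalog()] for
#' the pattern language). Each (sentence, rule) pair that matches yields one
#' SENTENCE suggestion carrying the rule's guidance and its fixed example;
#' the span covers the first match within the sentence.
#'
#' @param doc An `st_document`.
#' @param rules An `st_rule_catalog`.
#' @return A tibble with columns `kind`, `sentence`, `rule_id`, `token_first`,
#'   `token_last`, `char_start`, `char_end`, `matched`, `guidance`, `example`.
#' @export
match_sentence_rules <- function(doc, rules) {
  empty <- tibble::tibble(kind = character(), sentence = integer(),
                          rule_id = character(), token_first = integer(),
                          token_last = integer(), char_start = integer(),
                          char_end = integer(), matched = character(),
                          guidance = character(), example = character())
  if (nrow(rules) == 0L || nrow(doc$tokens) == 0L) return(empty)
  toks <- doc$tokens
  lower <- tolower(toks$surface)
  out <- list()
  for (s in seq_len(nrow(doc$sentences))) {
    idx <- seq.int(doc$sentences$first[s] + 1L, doc$sentences$last[s])
    widx <- idx[toks$is_word[idx]]
    for (r in seq_len(nrow(rules))) {
      m <- find_pattern_match(rules$matchers[[r]], widx, lower, toks$pos)
      if (is.null(m)) next
      first <- m[1]; last <- m[length(m)]
      out[[length(out) + 1L]] <- tibble::tibble(
        kind = "SENTENCE", sentence = s, rule_id = rules$id[r],
        token_first = first - 1L, token_last = last,
        char_start = toks$start[first], char_end = toks$end[last],
        matched = substr(doc$text, toks$start[first] + 1L, toks$end[last]),
        guidance = rules$guidance[r], example = rules$example[r]
      )
    }
  }
  if (length(out) == 0L) return(empty)
  do.call(rbind, out)
}

find_pattern_match <- function(matchers, word_idx, lower, pos) {
  m <- length(matchers)
  n <- length(word_idx)
  if (m > n) return(NULL)
  for (start in seq_len(n - m + 1L)) {
    ok <- TRUE
    for (j in seq_len(m)) {
      t <- word_idx[start + j - 1L]
      mt <- matchers[[j]]
      hit <- switch(mt$type,
                    literal = lower[t] == mt$value,
                    pos = pos[t] == mt$value,
                    regex = grepl(mt$value, lower[t], perl = TRUE))
      if (!hit) { ok <- FALSE; break }
    }
    if (ok) return(word_idx[start:(start + m - 1L)])
  }
  NULL
}

# ---- edits and the event log ------------------------------------------------

#' Apply an edit to a document
#'
#' Replaces the character range `[char_start, char_end)` (0-based, as in
#' suggestion spans) with `replacement` and re-tokenizes. Suggestions are
#' suggestions only: nothing is ever replaced automatically, this is the
#' operation behind an explicit user choice.
#'
#' @param doc An `st_document`.
#' @param char_start,char_end 0-based half-open character range.
#' @param replacement Replacement string (may be empty, i.e. deletion).
#' @return A new `st_document`.
#' @export
apply_edit <- function(doc, char_start, char_end, replacement) {
  stopifnot(inherits(doc, "st_document"),
            char_start >= 0, char_start <= char_end,
            char_end <= nchar(doc$text))
  tokenize(splice_text(doc$text, char_start, char_end, replacement))
}

splice_text <- function(text, start, end, replacement) {
  paste0(substr(text, 1L, start), replacement,
         substring(text, end + 1L))
}

#' Editing session with an append-only event log
#'
#' An `st_edit_session` tracks the current document, a version counter and
#' every edit applied, emulating the editor's server-side activity log
#' (which spans are clicked, which candidates are chosen). Replaying the log
#' over the original text reproduces the final text exactly; see
#' [replay_edits()].
#'
#' @param text Original text.
#' @return An `st_edit_session`.
#' @export
new_edit_session <- function(text) {
  structure(list(original_text = text, doc = tokenize(text),
                 version = 0L, events = list()),
            class = "st_edit_session")
}

#' @rdname new_edit_session
#' @param session An `st_edit_session`.
#' @param char_start,char_end 0-based half-open range in the session's
#'   current document.
#' @param replacement Replacement string (the chosen candidate or free text).
#' @param version The document version the span refers to; editing against a
#'   stale version is an error.
#' @export
session_edit <- function(session, char_start, char_end, replacement,
                         version = session$version) {
  stopifnot(inherits(session, "st_edit_session"))
  if (version != session$version) {
    stop("stale span: edit targets version ", version,
         " but session is at version ", session$version)
  }
  session$doc <- apply_edit(session$doc, char_start, char_end, replacement)
  event <- list(timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3%z"),
                char_start = char_start, char_end = char_end,
                replacement = replacement,
                version_before = session$version,
                version_after = session$version + 1L)
  session$version <- session$version + 1L
  session$events <- c(session$events, list(event))
  session
}

#' Replay an edit log
#'
#' @param original_text The text the log started from.
#' @param events List of edit events (as stored in a session, or read back
#'   with [read_edit_log()]).
#' @return The final text after applying every event in order.
#' @export
replay_edits <- function(original_text, events) {
  text <- original_text
  for (ev in events) {
    text <- splice_text(text, ev$char_start, ev$char_end, ev$replacement)
  }
  text
}

#' Write / read an edit log as JSON lines
#'
#' @param events List of edit events.
#' @param path File path.
#' @export
write_edit_log <- function(events, path) {
  lines <- vapply(events, function(ev) {
    as.character(jsonlite::toJSON(ev, auto_unbox = TRUE, digits = NA))
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_edit_log
#' @export
read_edit_log <- function(path) {
  lines <- read_resource_lines(path)
  lapply(lines, function(l) jsonlite::fromJSON(l, simplifyVector = TRUE))
}
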