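# Independent oracles used by the test suite. These deliberately use
# different algorithms from the package implementation.

# ROUGE-N by explicit position-marking overlap: for each answer n-gram,
# consume at most one unused matching reference n-gram (equivalent to
# clipped counting, computed without tables).
oracle_rouge_n <- function(answer, reference, n) {
  grams <- function(x) {
    if (length(x) < n) return(character(0))
    out <- character(length(x) - n + 1L)
    for (i in seq_along(out)) out[i] <- paste(x[i:(i + n - 1L)], collapse = "\r")
    out
  }
  ag <- grams(answer); rg <- grams(reference)
  used <- rep(FALSE, length(rg))
  overlap <- 0L
  for (g in ag) {
    hit <- which(!used & rg == g)
    if (length(hit)) {
      used[hit[1]] <- TRUE
      overlap <- overlap + 1L
    }
  }
  p <- if (length(ag)) overlap / length(ag) else 0
  r <- if (length(rg)) overlap / length(rg) else 0
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  list(precision = p, recall = r, f_measure = f)
}

# LCS by top-down memoized recursion (the package uses a bottom-up rolling
# row), then the same P/R/F construction.
oracle_rouge_l <- function(answer, reference) {
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (i == 0L || j == 0L) return(0L)
    key <- paste(i, j)
    hit <- get0(key, envir = memo)
    if (!is.null(hit)) return(hit)
    val <- if (answer[i] == reference[j]) {
      rec(i - 1L, j - 1L) + 1L
    } else {
      max(rec(i - 1L, j), rec(i, j - 1L))
    }
    assign(key, val, envir = memo)
    val
  }
  l <- rec(length(answer), length(reference))
  p <- if (length(answer)) l / length(answer) else 0
  r <- l / length(reference)
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  list(lcs = l, precision = p, recall = r, f_measure = f)
}

random_token_vector <- function(len, vocab = letters[1:6]) {
  sample(vocab, len, replace = TRUE)
}

# Hand-built embedding table on an explicit matrix.
toy_embeddings <- function(words, mat) {
  rownames(mat) <- words
  simpletext:::new_embedding_table(mat)
}

# In-memory substitution lexicon for engine tests.
toy_subs <- function(phrases, candidates, resource = "test") {
  simpletext:::new_substitution_lexicon(tibble::tibble(
    phrase = phrases, candidates = candidates,
    resource = rep(resource, length(phrases))))
}

toy_freq <- function(...) {
  simpletext:::new_frequency_lexicon(c(...))
}
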