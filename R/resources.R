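# Lexical resources consumed by the engine: a word-frequency lexicon (TSV),
# a word-embedding table (word2vec text format), a substitution lexicon (TSV)
# and a sentence-rule catalog (TSV). Every reader has a matching writer and
# write -> read is the identity.

#' Read a word-frequency lexicon
#'
#' The file format is one `word<TAB>count` pair per line (counts are corpus
#' occurrence counts; larger means more common, hence simpler). Words are
#' lowercased on load; duplicate words have their counts summed.
#'
#' @param path Path to a TSV file.
#' @return An `st_frequency_lexicon`: a named numeric vector of counts.
#' @export
read_frequency_list <- function(path) {
  lines <- read_resource_lines(path)
  if (length(lines) == 0L) return(new_frequency_lexicon(numeric(0)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1)) != 2L |
                 is.na(suppressWarnings(
                   as.numeric(vapply(parts, function(p) p[min(2L, length(p))],
                                     character(1))))))
  if (length(bad)) {
    stop("malformed frequency line ", bad[1], " in ", path, ": ",
         dQuote(lines[bad[1]]))
  }
  words <- tolower(vapply(parts, `[[`, character(1), 1L))
  counts <- as.numeric(vapply(parts, `[[`, character(1), 2L))
  if (any(counts < 0)) stop("negative count in frequency lexicon: ", path)
  merged <- tapply(counts, words, sum)
  lex <- as.numeric(merged)
  names(lex) <- names(merged)
  new_frequency_lexicon(lex)
}

new_frequency_lexicon <- function(x) {
  if (is.null(x)) x <- numeric(0)
  structure(x, class = c("st_frequency_lexicon", class(x)))
}

#' @rdname read_frequency_list
#' @param lexicon An `st_frequency_lexicon`.
#' @export
write_frequency_list <- function(lexicon, path) {
  writeLines(paste(names(lexicon), format_num(unclass(lexicon)), sep = "\t"),
             path, useBytes = TRUE)
  invisible(path)
}

#' Look up word frequencies
#'
#' @param lexicon An `st_frequency_lexicon`.
#' @param words Character vector (matched lowercased).
#' @param default Count for out-of-lexicon words.
#' @return Numeric vector of counts.
#' @export
word_frequency <- function(lexicon, words, default = NA_real_) {
  out <- unname(unclass(lexicon)[tolower(words)])
  out[is.na(out)] <- default
  out
}

# ---- embeddings -------------------------------------------------------------

#' Read a word-embedding table (word2vec text format)
#'
#' Expects a header line `"V D"` (vocabulary size, dimension) followed by `V`
#' lines of `word` plus `D` whitespace-separated floats. Keys are lowercased.
#' A line with the wrong number of values, or a vocabulary size that does not
#' match the header, is an error.
#'
#' @param path Path to the file.
#' @return An `st_embedding_table`: a `V x D` numeric matrix with words as
#'   row names.
#' @export
read_embeddings <- function(path) {
  lines <- read_resource_lines(path)
  if (length(lines) == 0L) stop("empty embedding file: ", path)
  header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(header) != 2L || anyNA(suppressWarnings(as.integer(header)))) {
    stop("embedding header must be 'V D', got: ", dQuote(lines[1]))
  }
  v <- as.integer(header[1]); d <- as.integer(header[2])
  body <- lines[-1]
  if (length(body) != v) {
    stop("embedding file declares ", v, " rows but has ", length(body))
  }
  mat <- matrix(NA_real_, nrow = v, ncol = d)
  words <- character(v)
  for (i in seq_len(v)) {
    parts <- strsplit(trimws(body[i]), "\\s+")[[1]]
    if (length(parts) != d + 1L) {
      stop("embedding line ", i + 1L, " has dimension ", length(parts) - 1L,
           ", expected ", d)
    }
    vals <- suppressWarnings(as.numeric(parts[-1]))
    if (anyNA(vals)) stop("non-numeric embedding value on line ", i + 1L)
    words[i] <- tolower(parts[1])
    mat[i, ] <- vals
  }
  rownames(mat) <- words
  new_embedding_table(mat)
}

new_embedding_table <- function(mat) {
  structure(mat, class = c("st_embedding_table", class(mat)))
}

#' @rdname read_embeddings
#' @param emb An `st_embedding_table`.
#' @export
write_embeddings <- function(emb, path) {
  header <- paste(nrow(emb), ncol(emb))
  rows <- vapply(seq_len(nrow(emb)), function(i) {
    paste(c(rownames(emb)[i], format_num(emb[i, ])), collapse = " ")
  }, character(1))
  writeLines(c(header, rows), path, useBytes = TRUE)
  invisible(path)
}

#' Look up an embedding vector
#'
#' @param emb An `st_embedding_table`.
#' @param word A word (matched lowercased).
#' @return The vector, or `NULL` if out of vocabulary.
#' @export
embedding_vector <- function(emb, word) {
  w <- tolower(word)
  if (!w %in% rownames(emb)) return(NULL)
  as.numeric(emb[w, ])
}

#' Cosine similarity between two vectors
#'
#' @param a,b Numeric vectors of equal length.
#' @return Cosine in `[-1, 1]`; `NA` if either vector has zero norm.
#' @export
cosine_similarity <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(NA_real_)
  sum(a * b) / (na * nb)
}

# ---- substitution lexicon ---------------------------------------------------

#' Read a substitution lexicon
#'
#' Format: `phrase<TAB>candidate|candidate|...` with an optional third column
#' naming the source resource (defaults to the file's base name, mirroring
#' the editor's per-resource checkboxes). Phrases may span several words;
#' candidate order is preserved — it is the lexicon's preference order and
#' breaks ties in context ranking. An entry with no candidates is an error.
#'
#' @param path Path to a TSV file.
#' @param resource Default resource tag for entries without one.
#' @return An `st_substitution_lexicon`: a tibble with columns `phrase`,
#'   `candidates` (list of character vectors), `resource`.
#' @export
read_substitution_lexicon <- function(path,
                                      resource = sub("\\.[^.]*$", "",
                                                     basename(path))) {
  lines <- read_resource_lines(path)
  if (length(lines) == 0L) {
    return(new_substitution_lexicon(
      tibble::tibble(phrase = character(), candidates = list(),
                     resource = character())))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- vapply(parts, length, integer(1))
  if (any(nf < 2L)) {
    stop("malformed substitution line ", which(nf < 2L)[1], " in ", path)
  }
  phrase <- tolower(trimws(vapply(parts, `[[`, character(1), 1L)))
  cands <- lapply(parts, function(p) {
    cl <- trimws(strsplit(p[2], "|", fixed = TRUE)[[1]])
    cl[nzchar(cl)]
  })
  empty <- which(vapply(cands, length, integer(1)) == 0L | !nzchar(phrase))
  if (length(empty)) {
    stop("substitution entry with empty phrase or candidate list on line ",
         empty[1], " in ", path)
  }
  res <- vapply(parts, function(p) if (length(p) >= 3L) p[3] else resource,
                character(1))
  new_substitution_lexicon(
    tibble::tibble(phrase = phrase, candidates = cands, resource = res))
}

new_substitution_lexicon <- function(tbl) {
  structure(tbl, class = c("st_substitution_lexicon", class(tbl)))
}

#' @rdname read_substitution_lexicon
#' @param lexicon An `st_substitution_lexicon`.
#' @export
write_substitution_lexicon <- function(lexicon, path) {
  writeLines(paste(lexicon$phrase,
                   vapply(lexicon$candidates, paste, character(1),
                          collapse = "|"),
                   lexicon$resource, sep = "\t"),
             path, useBytes = TRUE)
  invisible(path)
}

#' Merge substitution lexicons / keep only enabled resources
#'
#' Mirrors the editor's resource checkbox panel: all loaded resources are
#' active by default and any subset can be switched off.
#'
#' @param ... `st_substitution_lexicon` objects.
#' @param enabled `NULL` (all) or character vector of resource tags to keep.
#' @return An `st_substitution_lexicon`.
#' @export
combine_substitution_lexicons <- function(..., enabled = NULL) {
  tbl <- do.call(rbind, lapply(list(...), function(x) {
    tibble::as_tibble(unclass(x)[c("phrase", "candidates", "resource")])
  }))
  if (!is.null(enabled)) tbl <- tbl[tbl$resource %in% enabled, , drop = FALSE]
  new_substitution_lexicon(tibble::as_tibble(tbl))
}

# ---- sentence-rule catalog --------------------------------------------------

#' Read a sentence-rule catalog
#'
#' Format: `id<TAB>pattern<TAB>guidance<TAB>example` per line. A pattern is a
#' whitespace-separated sequence of token matchers; each matcher is either a
#' literal lowercased surface (`months`), a coarse POS tag in angle brackets
#' (`<NOUN>`), or a regular expression between slashes applied to the
#' lowercased surface (`/tion$/`). Guidance and example must be non-empty and
#' the pattern must compile; the example is fixed per rule — it is generic
#' writing guidance, not adapted to any particular text.
#'
#' @param path Path to a TSV file.
#' @return An `st_rule_catalog`: a tibble with columns `id`, `pattern`,
#'   `guidance`, `example`, `matchers` (compiled, list column).
#' @export
read_rule_catalog <- function(path) {
  lines <- read_resource_lines(path)
  if (length(lines) == 0L) {
    return(new_rule_catalog(
      tibble::tibble(id = character(), pattern = character(),
                     guidance = character(), example = character(),
                     matchers = list())))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- vapply(parts, length, integer(1))
  if (any(nf != 4L)) {
    stop("rule line ", which(nf != 4L)[1], " in ", path,
         " must have 4 tab-separated fields")
  }
  tbl <- tibble::tibble(
    id = vapply(parts, `[[`, character(1), 1L),
    pattern = vapply(parts, `[[`, character(1), 2L),
    guidance = vapply(parts, `[[`, character(1), 3L),
    example = vapply(parts, `[[`, character(1), 4L)
  )
  if (any(!nzchar(tbl$guidance) | !nzchar(tbl$example))) {
    stop("rule with empty guidance or example in ", path)
  }
  tbl$matchers <- lapply(tbl$pattern, compile_rule_pattern)
  new_rule_catalog(tbl)
}

new_rule_catalog <- function(tbl) {
  structure(tbl, class = c("st_rule_catalog", class(tbl)))
}

#' @rdname read_rule_catalog
#' @param rules An `st_rule_catalog`.
#' @export
write_rule_catalog <- function(rules, path) {
  writeLines(paste(rules$id, rules$pattern, rules$guidance, rules$example,
                   sep = "\t"),
             path, useBytes = TRUE)
  invisible(path)
}

POS_TAGS <- c("NOUN", "VERB", "ADJ", "ADV", "OTHER", "PUNCT")

compile_rule_pattern <- function(pattern) {
  items <- strsplit(trimws(pattern), "\\s+")[[1]]
  if (length(items) == 0L) stop("empty rule pattern")
  lapply(items, function(it) {
    if (grepl("^<[A-Z]+>$", it)) {
      tag <- sub("^<([A-Z]+)>$", "\\1", it)
      if (!tag %in% POS_TAGS) stop("unknown POS tag in pattern: ", it)
      list(type = "pos", value = tag)
    } else if (nchar(it) > 2L && startsWith(it, "/") && endsWith(it, "/")) {
      re <- substr(it, 2L, nchar(it) - 1L)
      ok <- tryCatch({ grepl(re, "x", perl = TRUE); TRUE },
                     error = function(e) FALSE,
                     warning = function(w) FALSE)
      if (!ok) stop("rule regex does not compile: ", it)
      list(type = "regex", value = re)
    } else {
      list(type = "literal", value = tolower(it))
    }
  })
}

# ---- shared helpers ---------------------------------------------------------

read_resource_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines[nzchar(trimws(lines))]
}

format_num <- function(x) {
  vapply(x, function(v) format(v, scientific = FALSE, trim = TRUE,
                               digits = 15), character(1))
}
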