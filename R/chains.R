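# Lexical chains: sequences of related nouns running through a text, a
# cohesion indicator. Three match levels of increasing breadth — exact
# (same lemma), synonym (shared synonym set), semantic (embedding cosine).

CHAIN_LEVELS <- c("EXACT", "SYNONYM", "SEMANTIC")

#' Build lexical chains
#'
#' Scans the document's NOUN tokens in order and attaches each to the most
#' recently updated chain that contains a related member; if none exists a
#' new chain is opened. Relatedness by level: `EXACT` — same lemma;
#' `SYNONYM` — same lemma or a shared synonym-set id; `SEMANTIC` — the
#' synonym criteria or embedding cosine at least `theta`. Only chains with at
#' least two members are returned (singletons are not chains).
#'
#' @param doc An `st_document`.
#' @param level `"EXACT"`, `"SYNONYM"` or `"SEMANTIC"` (case-insensitive).
#' @param synonyms Named character vector mapping lemma -> synonym-set id
#'   (used at SYNONYM and SEMANTIC levels).
#' @param emb An `st_embedding_table`; required at SEMANTIC level.
#' @param theta Cosine threshold in `[-1, 1]` for SEMANTIC chaining.
#' @return An `st_chains` tibble with columns `chain_id`, `level`, `head`
#'   (lemma of the first member), `members` (list of 1-based token indices,
#'   strictly increasing), `length`, `first`, `last` (position span).
#' @export
build_chains <- function(doc, level = c("EXACT", "SYNONYM", "SEMANTIC"),
                         synonyms = NULL, emb = NULL, theta = 0.6) {
  level <- match.arg(toupper(level[1]), CHAIN_LEVELS)
  if (theta < -1 || theta > 1) stop("theta must lie in [-1, 1], got ", theta)
  if (level == "SEMANTIC" && is.null(emb)) {
    stop("SEMANTIC chaining requires an embedding table")
  }
  toks <- doc$tokens
  noun_idx <- which(toks$pos == "NOUN" & toks$is_word)

  chains <- list()        # each: list(members = int vector, lemmas, updated)
  tick <- 0L
  for (t in noun_idx) {
    lem <- toks$lemma[t]
    surf <- tolower(toks$surface[t])
    attach_to <- NA_integer_
    if (length(chains)) {
      recency <- order(vapply(chains, `[[`, integer(1), "updated"),
                       decreasing = TRUE)
      for (ci in recency) {
        if (chain_related(chains[[ci]], lem, surf, level, synonyms, emb,
                          theta, toks)) {
          attach_to <- ci
          break
        }
      }
    }
    tick <- tick + 1L
    if (is.na(attach_to)) {
      chains[[length(chains) + 1L]] <- list(members = t, updated = tick)
    } else {
      chains[[attach_to]]$members <- c(chains[[attach_to]]$members, t)
      chains[[attach_to]]$updated <- tick
    }
  }
  chains <- Filter(function(ch) length(ch$members) >= 2L, chains)
  tbl <- tibble::tibble(
    chain_id = seq_along(chains),
    level = rep(level, length(chains)),
    head = vapply(chains, function(ch) toks$lemma[ch$members[1]], character(1)),
    members = lapply(chains, `[[`, "members"),
    length = vapply(chains, function(ch) length(ch$members), integer(1)),
    first = vapply(chains, function(ch) min(ch$members), integer(1)),
    last = vapply(chains, function(ch) max(ch$members), integer(1))
  )
  structure(tbl, class = c("st_chains", class(tbl)))
}

chain_related <- function(chain, lem, surf, level, synonyms, emb, theta, toks) {
  for (m in chain$members) {
    mlem <- toks$lemma[m]
    if (mlem == lem) return(TRUE)
    if (level %in% c("SYNONYM", "SEMANTIC") && !is.null(synonyms)) {
      a <- synonyms[lem]; b <- synonyms[mlem]
      if (!is.na(a) && !is.na(b) && a == b) return(TRUE)
    }
    if (level == "SEMANTIC") {
      va <- embedding_vector(emb, surf)
      if (is.null(va)) va <- embedding_vector(emb, lem)
      msurf <- tolower(toks$surface[m])
      vb <- embedding_vector(emb, msurf)
      if (is.null(vb)) vb <- embedding_vector(emb, mlem)
      if (!is.null(va) && !is.null(vb)) {
        cs <- cosine_similarity(va, vb)
        if (!is.na(cs) && cs >= theta) return(TRUE)
      }
    }
  }
  FALSE
}

#' Chain statistics
#'
#' Summary statistics over one document's chains, including the crossing-pair
#' count: two chains cross iff their position spans interleave without
#' nesting, i.e. ordering so that `min(A) < min(B)`,
#' `min(B) <= max(A) < max(B)`. More crossing chains indicate harder,
#' less cohesive text.
#'
#' @param chains An `st_chains` tibble from [build_chains()].
#' @return A list with `chain_count`, `mean_length`, `spans` (tibble of
#'   first/last per chain), `crossing_pair_count`.
#' @export
chain_stats <- function(chains) {
  n <- nrow(chains)
  crossing <- 0L
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        a <- c(chains$first[i], chains$last[i])
        b <- c(chains$first[j], chains$last[j])
        if (a[1] > b[1]) { tmp <- a; a <- b; b <- tmp }
        if (a[1] < b[1] && b[1] <= a[2] && a[2] < b[2]) {
          crossing <- crossing + 1L
        }
      }
    }
  }
  list(chain_count = n,
       mean_length = if (n) mean(chains$length) else NA_real_,
       spans = tibble::tibble(chain_id = chains$chain_id,
                              first = chains$first, last = chains$last),
       crossing_pair_count = crossing)
}
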