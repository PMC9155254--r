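# Deterministic synthetic-data generator: toy lexical resources with a
# designed embedding geometry, and participant-response tables whose
# statistical structure mirrors the two-condition study design — so every
# module is testable without any external download.

TEXT_IDS <- c("asthma", "cirrhosis", "pemphigus", "polycythemia")

# Likert ~ a latent normal per condition discretized to 1..4; binary question
# items ~ Bernoulli per condition; recall metrics ~ clamped normals. Default
# parameter values are the study conditions of the two-condition reading
# experiment this generator emulates (49 participants, 4 texts each, 2
# original + 2 simplified, 6 counterbalanced combinations, ~21% of readings
# faster than the 60 s cutoff).
default_measure_params <- function() {
  bin <- function(po, ps) list(type = "binary", p = c(po, ps))
  num <- function(mo, so, ms, ss, lo = -Inf, hi = Inf, digits = NA) {
    list(type = "numeric", mean = c(mo, ms), sd = c(so, ss),
         lo = lo, hi = hi, digits = digits)
  }
  list(
    likert = list(type = "likert", mean = c(2.28, 2.55), sd = c(0.697, 0.681)),
    tf_before_1 = bin(0.67, 0.63), tf_before_2 = bin(0.71, 0.71),
    tf_before_3 = bin(0.51, 0.53), tf_before_4 = bin(0.76, 0.72),
    tf_before_5 = bin(0.33, 0.59),
    mc_while_1 = bin(0.80, 0.83), mc_while_2 = bin(0.71, 0.70),
    tf_after_1 = bin(0.66, 0.62), tf_after_2 = bin(0.93, 0.88),
    tf_after_3 = bin(0.66, 0.72), tf_after_4 = bin(0.93, 0.92),
    tf_after_5 = bin(0.52, 0.78),
    mc_after_1 = bin(0.37, 0.57), mc_after_2 = bin(0.68, 0.75),
    mc_after_3 = bin(0.33, 0.59), mc_after_4 = bin(0.33, 0.29),
    unique_word_count = num(25, 14, 23, 12, lo = 1, hi = Inf, digits = 0),
    prop_similar = num(0.76, 0.16, 0.82, 0.11, lo = 0, hi = 1),
    prop_matching = num(0.53, 0.18, 0.59, 0.14, lo = 0, hi = 1),
    cosine_similarity = num(0.111, 0.013, 0.117, 0.009, lo = -1, hi = 1),
    correct_facts = num(7.5, 4.4, 8.1, 6.6, lo = 0, hi = Inf, digits = 0),
    main_point = bin(0.67, 0.67),
    completeness = num(2.10, 0.89, 2.17, 0.84, lo = 0, hi = 4, digits = 0),
    correctness = num(3.18, 0.86, 3.21, 0.71, lo = 0, hi = 4, digits = 0),
    rouge_l_recall = num(0.0931, 0.0635, 0.1078, 0.0699, lo = 0, hi = 1),
    rouge_l_precision = num(0.4874, 0.2120, 0.4357, 0.1250, lo = 0, hi = 1),
    rouge_l_f = num(0.1514, 0.0954, 0.1637, 0.0903, lo = 0, hi = 1),
    rouge_1_recall = num(0.0851, 0.0506, 0.1187, 0.0802, lo = 0, hi = 1),
    rouge_1_precision = num(0.6893, 0.1517, 0.6536, 0.1330, lo = 0, hi = 1),
    rouge_1_f = num(0.1465, 0.0785, 0.1907, 0.1108, lo = 0, hi = 1),
    rouge_2_recall = num(0.0369, 0.0375, 0.0437, 0.0394, lo = 0, hi = 1),
    rouge_2_precision = num(0.3156, 0.2633, 0.2401, 0.1445, lo = 0, hi = 1),
    rouge_2_f = num(0.0640, 0.0638, 0.0699, 0.0562, lo = 0, hi = 1)
  )
}

#' Synthetic study configuration
#'
#' Configuration for [make_responses()]. Defaults are the emulated study's
#' conditions: 49 participants, 4 texts each (2 original, 2 simplified) over
#' 6 counterbalanced combinations, a 41/196 fraction of too-fast readings,
#' and per-measure condition parameters (Likert latent means 2.28 vs 2.55
#' etc.). `null_effects = TRUE` removes every condition effect by copying
#' the ORIGINAL parameters onto the SIMPLIFIED condition — the configuration
#' under which the analysis pipeline's type-I error is assessed.
#'
#' @param seed Integer seed; the same seed yields byte-identical output.
#' @param n_participants Number of participants.
#' @param fast_reader_fraction Probability that a reading is faster than the
#'   exclusion cutoff.
#' @param null_effects Remove all condition effects.
#' @param measure_params Per-measure parameter list; see
#'   `simpletext:::default_measure_params()` for the structure.
#' @return A list of class `st_synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L, n_participants = 49L,
                             fast_reader_fraction = 41 / 196,
                             null_effects = FALSE,
                             measure_params = default_measure_params()) {
  stopifnot(n_participants >= 1L, fast_reader_fraction >= 0,
            fast_reader_fraction < 1)
  if (null_effects) {
    measure_params <- lapply(measure_params, function(mp) {
      if (mp$type == "binary") mp$p[2] <- mp$p[1]
      else { mp$mean[2] <- mp$mean[1]; mp$sd[2] <- mp$sd[1] }
      mp
    })
  }
  structure(list(seed = as.integer(seed),
                 n_participants = as.integer(n_participants),
                 fast_reader_fraction = fast_reader_fraction,
                 measure_params = measure_params),
            class = "st_synthetic_config")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate the toy lexical resources
#'
#' Writes a frequency lexicon, an embedding table (word2vec text format), a
#' substitution lexicon and a sentence-rule catalog into `dir`. The
#' embeddings are unit-norm vectors with a designed geometry: each
#' difficult word and its substitution candidates share a cluster direction
#' (pairwise cosine >= 0.9 by construction) and distinct clusters are built
#' on orthogonal coordinates, so distractor pairs have cosine near 0.
#' Deterministic: the same seed yields byte-identical files.
#'
#' @param dir Output directory (created if missing).
#' @param seed Integer seed.
#' @return Named list of the four file paths, invisibly usable by every
#'   resource reader.
#' @export
make_resources <- function(dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  clusters <- list(
    use = c("utilize", "use", "employ", "apply"),
    later = c("subsequent", "later", "following", "afterwards"),
    doctor = c("physician", "doctor", "clinician"),
    lung = c("pulmonary", "lung", "airway", "breathing"),
    start = c("commence", "begin", "start"),
    tired = c("fatigue", "tiredness", "exhaustion"),
    # distractor clusters, unrelated to any substitution
    animal = c("cat", "dog", "bird"),
    number = c("seven", "nine", "twelve")
  )
  easy <- c("the", "a", "an", "and", "or", "of", "to", "in", "is", "was",
            "it", "for", "can", "may", "help", "person", "people", "time",
            "body", "blood", "water", "air", "home", "day", "good", "make")
  hard <- c("utilize", "subsequent", "physician", "pulmonary", "commence",
            "fatigue", "cirrhosis", "pemphigus", "polycythemia",
            "exacerbation", "hypertension")

  dim <- 2L * length(clusters)
  words <- character(0); vecs <- list()
  with_seed(seed, {
    for (ci in seq_along(clusters)) {
      base <- numeric(dim); base[2L * ci - 1L] <- 1
      aux <- numeric(dim); aux[2L * ci] <- 1
      members <- clusters[[ci]]
      for (mi in seq_along(members)) {
        # small in-cluster spread on the auxiliary axis: cosine >= 0.9 kept
        v <- base + (mi - 1L) * 0.15 * aux
        v <- v / sqrt(sum(v^2))
        words <- c(words, members[mi])
        vecs[[length(vecs) + 1L]] <- round(v, 6)
      }
    }
    filler <- setdiff(easy, words)
    for (w in filler) {
      v <- stats::rnorm(dim)
      v <- round(v / sqrt(sum(v^2)), 6)
      words <- c(words, w)
      vecs[[length(vecs) + 1L]] <- v
    }
  })
  emb <- new_embedding_table(
    matrix(unlist(vecs), nrow = length(words), byrow = TRUE,
           dimnames = list(words, NULL)))

  counts <- c(stats::setNames(rep(10000, length(easy)), easy),
              stats::setNames(rep(10, length(hard)), hard),
              stats::setNames(rep(5000, length(c("doctor", "later", "begin",
                                                 "start", "lung"))),
                              c("doctor", "later", "begin", "start", "lung")))
  freq <- new_frequency_lexicon(counts[!duplicated(names(counts))])

  subs <- new_substitution_lexicon(tibble::tibble(
    phrase = c("utilize", "subsequent", "physician", "pulmonary",
               "commence", "fatigue", "myocardial infarction"),
    candidates = list(c("use"), c("later", "following", "followed by"),
                      c("doctor"), c("lung"), c("begin", "start"),
                      c("tiredness"), c("heart attack")),
    resource = rep("toy", 7)
  ))

  rules <- new_rule_catalog(tibble::tibble(
    id = c("nominalization", "duration-phrase"),
    pattern = c("/(tion|ment|ance|ence|ization)$/ of", "months or years"),
    guidance = c(
      "Replace the noun made from a verb with the verb itself.",
      "Rephrase vague durations; say how long things take in plain terms."),
    example = c(
      "Utilization of floss helps gums. -> Using floss helps gums.",
      "Damage happens over months or years. -> Damage happens slowly, over a long time."),
    matchers = list(NULL, NULL)
  ))
  rules$matchers <- lapply(rules$pattern, compile_rule_pattern)

  paths <- list(frequency = file.path(dir, "frequency.tsv"),
                embeddings = file.path(dir, "embeddings.txt"),
                substitutions = file.path(dir, "substitutions.tsv"),
                rules = file.path(dir, "rules.tsv"))
  write_frequency_list(freq, paths$frequency)
  write_embeddings(emb, paths$embeddings)
  write_substitution_lexicon(subs, paths$substitutions)
  write_rule_catalog(rules, paths$rules)
  paths
}

# The 6 counterbalanced combinations: which 2 of the 4 texts a participant
# reads in ORIGINAL form (the other 2 are SIMPLIFIED).
combination_table <- function() {
  utils::combn(4L, 2L)
}

#' Generate synthetic participant responses
#'
#' One row per participant-by-text reading, with the schema the analysis
#' pipeline consumes: identifiers, condition, reading time, the Likert
#' rating, the 16 question items, the automated recall metrics, the expert
#' scores and per-participant demographics. Condition effects, question
#' difficulties and the fast-reader fraction come from the configuration;
#' everything is drawn deterministically from its seed.
#'
#' @param config An `st_synthetic_config`.
#' @return A tibble of `n_participants * 4` rows.
#' @examples
#' resp <- make_responses(synthetic_config(seed = 7))
#' nrow(resp)  # 196
#' @export
make_responses <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "st_synthetic_config"))
  mp <- config$measure_params
  combos <- combination_table()
  n <- config$n_participants
  with_seed(config$seed, {
    edu_probs <- c(1, 11, 7, 13, 11, 2) / 45    # ordinal 1..6
    lang_probs <- c(0, 1, 3, 14, 27) / 45       # ordinal 1..5
    combo <- ((seq_len(n) - 1L) %% 6L) + 1L
    edu <- sample.int(6L, n, replace = TRUE, prob = edu_probs)
    lang <- sample.int(5L, n, replace = TRUE, prob = lang_probs)
    # per participant: which of the 4 texts, in randomized presentation order
    text_ix <- unlist(lapply(seq_len(n), function(p) sample.int(4L)))
    pid <- rep(seq_len(n), each = 4L)
    is_original <- vapply(seq_along(text_ix), function(i) {
      text_ix[i] %in% combos[, combo[pid[i]]]
    }, logical(1))
    m <- n * 4L
    ci <- ifelse(is_original, 1L, 2L)
    fast <- stats::runif(m) < config$fast_reader_fraction
    reading <- ifelse(fast, stats::runif(m, 15, 59.9),
                      60 + stats::rlnorm(m, meanlog = log(60), sdlog = 0.6))
    out <- tibble::tibble(
      participant_id = sprintf("P%02d", pid),
      text_id = TEXT_IDS[text_ix],
      combination = combo[pid],
      condition = ifelse(is_original, "ORIGINAL", "SIMPLIFIED"),
      reading_seconds = round(reading, 1),
      education_level = edu[pid],
      language_level = lang[pid]
    )
    for (mname in names(mp)) {
      out[[mname]] <- draw_measure(mp[[mname]], ci)
    }
    out
  })
}

# Vectorized draw of one measure; ci is the per-row condition index (1 or 2).
draw_measure <- function(mparam, ci) {
  m <- length(ci)
  if (mparam$type == "binary") {
    stats::rbinom(m, 1L, mparam$p[ci])
  } else if (mparam$type == "likert") {
    x <- round(stats::rnorm(m, mparam$mean[ci], mparam$sd[ci]))
    pmin(4L, pmax(1L, as.integer(x)))
  } else {
    x <- stats::rnorm(m, mparam$mean[ci], mparam$sd[ci])
    x <- pmin(mparam$hi, pmax(mparam$lo, x))
    if (!is.na(mparam$digits)) x <- round(x, mparam$digits)
    x
  }
}

#' Expected discretized Likert means of a configuration
#'
#' Closed-form ground truth for parameter-recovery checks: the mean of the
#' latent normal discretized to 1..4 (cutpoints 1.5, 2.5, 3.5), per
#' condition.
#'
#' @param config An `st_synthetic_config`.
#' @return Named numeric vector `c(ORIGINAL = ..., SIMPLIFIED = ...)`.
#' @export
expected_likert_means <- function(config = synthetic_config()) {
  mp <- config$measure_params$likert
  out <- vapply(1:2, function(ci) {
    mu <- mp$mean[ci]; s <- mp$sd[ci]
    cuts <- c(-Inf, 1.5, 2.5, 3.5, Inf)
    probs <- diff(stats::pnorm(cuts, mu, s))
    sum(1:4 * probs)
  }, numeric(1))
  stats::setNames(out, CONDITIONS)
}

#' Write / read a responses table as CSV
#'
#' @param responses Tibble from [make_responses()].
#' @param path File path.
#' @export
write_responses <- function(responses, path) {
  utils::write.csv(responses, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_responses
#' @export
read_responses <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
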