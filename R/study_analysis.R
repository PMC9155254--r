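# Study pipeline: reading-time response filtering, one-way ANOVA over the
# two text conditions, one-tailed Pearson correlations with Bonferroni
# correction, and condition-wise report tables.

CONDITIONS <- c("ORIGINAL", "SIMPLIFIED")

# Question item columns of a response table, in presentation order.
QUESTION_COLUMNS <- list(
  before = paste0("tf_before_", 1:5),
  while_reading = paste0("mc_while_", 1:2),
  after_tf = paste0("tf_after_", 1:5),
  after_mc = paste0("mc_after_", 1:4)
)

# Report rows: column name, display label, whether shown on the percent scale.
REPORT_MEASURES <- local({
  q <- QUESTION_COLUMNS
  rbind(
    data.frame(column = "likert", label = "4-point Likert scale", pct = FALSE),
    data.frame(column = q$before, label = paste0("TF", 1:5, " (before)"),
               pct = TRUE),
    data.frame(column = q$while_reading,
               label = c("Overview question (while)", "General question (while)"),
               pct = TRUE),
    data.frame(column = q$after_tf, label = paste0("TF", 1:5, " (after)"),
               pct = TRUE),
    data.frame(column = q$after_mc, label = paste0("MC", 1:4, " (after)"),
               pct = TRUE),
    data.frame(column = c("unique_word_count", "prop_similar", "prop_matching",
                          "cosine_similarity"),
               label = c("Unique word count (N)",
                         "Proportion of words similar to text (%)",
                         "Proportion of words matching text (%)",
                         "Overall cosine similarity"),
               pct = c(FALSE, TRUE, TRUE, FALSE)),
    data.frame(column = c("correct_facts", "main_point", "completeness",
                          "correctness"),
               label = c("Correct facts count (N)", "Main point made (%)",
                         "Completeness (score)", "Correctness (score)"),
               pct = c(FALSE, TRUE, FALSE, FALSE)),
    data.frame(column = c("rouge_l_recall", "rouge_l_precision", "rouge_l_f",
                          "rouge_1_recall", "rouge_1_precision", "rouge_1_f",
                          "rouge_2_recall", "rouge_2_precision", "rouge_2_f"),
               label = c("ROUGE recall - longest phrase",
                         "ROUGE precision - longest phrase",
                         "ROUGE F-measure - longest phrase",
                         "ROUGE recall - unigram", "ROUGE precision - unigram",
                         "ROUGE F-measure - unigram",
                         "ROUGE recall - bigram", "ROUGE precision - bigram",
                         "ROUGE F-measure - bigram"),
               pct = FALSE)
  )
})

#' Filter responses by reading time
#'
#' Excludes a participant-by-text record iff less than `min_seconds` was
#' spent reading the text and its two while-reading questions. Exclusion is
#' per text: a participant's other texts are kept. A record with missing
#' timing is retained but flagged (`flag_missing_timing`), never silently
#' dropped. At exactly `min_seconds` the record is retained (the cutoff is
#' strictly "less than one minute").
#'
#' @param records A response data frame with a `reading_seconds` column.
#' @param min_seconds Exclusion cutoff, default 60.
#' @return A list with elements `retained` and `excluded` (both tibbles;
#'   `retained` gains a `flag_missing_timing` column).
#' @export
filter_responses <- function(records, min_seconds = 60) {
  stopifnot("reading_seconds" %in% names(records))
  missing <- is.na(records$reading_seconds)
  fast <- !missing & records$reading_seconds < min_seconds
  retained <- tibble::as_tibble(records[!fast, , drop = FALSE])
  retained$flag_missing_timing <- missing[!fast]
  list(retained = retained,
       excluded = tibble::as_tibble(records[fast, , drop = FALSE]))
}

#' One-way analysis of variance (two or more groups)
#'
#' Classic between/within sum-of-squares decomposition,
#' `F = MS_between / MS_within`, with the p-value from the upper tail of the
#' F distribution. Degenerate cases: zero within-group variance with equal
#' group means gives `F = 0, p = 1`; with unequal means the statistic
#' diverges and is reported as `Inf` with `p = 0`.
#'
#' @param values Numeric vector of observations.
#' @param groups Factor or character vector of the same length.
#' @return An `st_anova` list: `group_means`, `group_sds`, `group_ns`, `F`,
#'   `p`, `df_between`, `df_within`, `ms_between`, `ms_within`.
#' @examples
#' one_way_anova(c(1, 2, 3, 2, 3, 4), rep(c("a", "b"), each = 3))
#' @export
one_way_anova <- function(values, groups) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- factor(groups[keep])
  ns <- tapply(values, groups, length)
  if (nlevels(groups) < 2L || any(ns < 2L)) {
    stop("one_way_anova() needs at least 2 groups with >= 2 observations each")
  }
  means <- tapply(values, groups, mean)
  sds <- tapply(values, groups, stats::sd)
  grand <- mean(values)
  ssb <- sum(ns * (means - grand)^2)
  ssw <- sum((values - means[groups])^2)
  dfb <- nlevels(groups) - 1L
  dfw <- length(values) - nlevels(groups)
  msb <- ssb / dfb
  msw <- ssw / dfw
  if (msw == 0) {
    f <- if (msb == 0) 0 else Inf
    p <- if (msb == 0) 1 else 0
  } else {
    f <- msb / msw
    p <- stats::pf(f, dfb, dfw, lower.tail = FALSE)
  }
  structure(list(group_means = means, group_sds = sds, group_ns = ns,
                 F = f, p = p, df_between = dfb, df_within = dfw,
                 ms_between = msb, ms_within = msw),
            class = "st_anova")
}

#' @export
print.st_anova <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              x$df_between, x$df_within, x$F, x$p))
  invisible(x)
}

#' One-tailed Pearson correlation (positive association)
#'
#' Pearson r with the upper-tail p-value of the t transform
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom,
#' testing against the one-sided alternative of positive association.
#'
#' @param x,y Numeric vectors, `n >= 3`, each with nonzero variance.
#' @return A list with `r`, `p`, `n`, `df`.
#' @export
pearson_one_tailed <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("pearson_one_tailed() needs n >= 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("pearson_one_tailed() requires nonzero variance in both variables")
  }
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tstat <- if (abs(r) >= 1) sign(r) * Inf else r * sqrt((n - 2) / (1 - r^2))
  p <- stats::pt(tstat, df = n - 2, lower.tail = FALSE)
  list(r = r, p = p, n = n, df = n - 2L)
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise level in `(0, 1)`.
#' @param m Number of tests, `>= 1`.
#' @return `alpha / m` (0.0125 for alpha 0.05 over 4 tests).
#' @export
bonferroni_threshold <- function(alpha = 0.05, m = 1L) {
  stopifnot(alpha > 0, alpha < 1, m >= 1, m == as.integer(m))
  alpha / m
}

#' Condition-wise study report
#'
#' One row per measure with the mean (SD) in each condition and the one-way
#' ANOVA F and p across conditions — the shape of the study's result tables.
#' Binary items are reported on the percent scale. A measure missing in a
#' condition, or with too few observations for the ANOVA, is flagged rather
#' than fabricated.
#'
#' @param records Filtered response records (see [filter_responses()]).
#' @return A tibble with columns `measure`, `column`, `mean_original`,
#'   `sd_original`, `mean_simplified`, `sd_simplified`, `F`, `p`, `flag`.
#' @export
build_report <- function(records) {
  stopifnot(all(c("condition") %in% names(records)))
  rows <- lapply(seq_len(nrow(REPORT_MEASURES)), function(i) {
    col <- REPORT_MEASURES$column[i]
    scale <- if (REPORT_MEASURES$pct[i]) 100 else 1
    base <- tibble::tibble(measure = REPORT_MEASURES$label[i], column = col,
                           mean_original = NA_real_, sd_original = NA_real_,
                           mean_simplified = NA_real_,
                           sd_simplified = NA_real_,
                           F = NA_real_, p = NA_real_, flag = NA_character_)
    if (!col %in% names(records)) {
      base$flag <- "missing_column"
      return(base)
    }
    v <- as.numeric(records[[col]]) * scale
    g <- records$condition
    for (cond in CONDITIONS) {
      vals <- v[g == cond & !is.na(v)]
      pre <- if (cond == "ORIGINAL") "original" else "simplified"
      if (length(vals) == 0L) {
        base$flag <- "empty_condition_cell"
      } else {
        base[[paste0("mean_", pre)]] <- mean(vals)
        base[[paste0("sd_", pre)]] <- stats::sd(vals)
      }
    }
    if (is.na(base$flag)) {
      aov_res <- tryCatch(one_way_anova(v, g), error = function(e) NULL)
      if (is.null(aov_res)) {
        base$flag <- "anova_not_estimable"
      } else {
        base$F <- aov_res$F
        base$p <- aov_res$p
      }
    }
    base
  })
  do.call(rbind, rows)
}

#' Per-participant question accuracy
#'
#' Mean accuracy over the question items answered with and after reading the
#' text — the two while-reading multiple-choice items, the five repeated
#' true/false items and the four after-reading multiple-choice items — i.e.
#' excluding the five before-reading questions. Set `mc_only = TRUE` to
#' restrict to the six multiple-choice items proper.
#'
#' @param records Response records.
#' @param mc_only Use only the while/after multiple-choice items.
#' @param condition Optional condition filter (`"ORIGINAL"`/`"SIMPLIFIED"`).
#' @return A tibble `participant_id`, `accuracy`, plus the participant's
#'   `education_level` and `language_level` when present.
#' @export
question_accuracy <- function(records, mc_only = FALSE, condition = NULL) {
  cols <- if (mc_only) {
    c(QUESTION_COLUMNS$while_reading, QUESTION_COLUMNS$after_mc)
  } else {
    c(QUESTION_COLUMNS$while_reading, QUESTION_COLUMNS$after_tf,
      QUESTION_COLUMNS$after_mc)
  }
  stopifnot(all(cols %in% names(records)))
  if (!is.null(condition)) {
    records <- records[records$condition %in% condition, , drop = FALSE]
  }
  acc <- rowMeans(as.matrix(records[, cols]), na.rm = TRUE)
  agg <- tapply(acc, records$participant_id, mean)
  out <- tibble::tibble(participant_id = names(agg),
                        accuracy = as.numeric(agg))
  for (dem in c("education_level", "language_level")) {
    if (dem %in% names(records)) {
      d <- tapply(records[[dem]], records$participant_id, `[`, 1L)
      out[[dem]] <- as.numeric(d[out$participant_id])
    }
  }
  out
}

#' Demographic correlation analysis
#'
#' One-tailed Pearson correlations of per-participant question accuracy
#' (excluding before-reading items) with self-reported education level
#' (ordinal 1-6) and language-at-home level (ordinal 1-5), overall and
#' within each condition — with the Bonferroni-corrected level for the four
#' per-condition tests.
#'
#' @param records Filtered response records.
#' @param alpha Family-wise level, default 0.05.
#' @return A tibble `subset`, `demographic`, `r`, `p`, `n`, plus attribute
#'   `bonferroni` = `alpha / 4`.
#' @export
demographic_correlations <- function(records, alpha = 0.05) {
  subsets <- list(overall = NULL, original = "ORIGINAL",
                  simplified = "SIMPLIFIED")
  rows <- list()
  for (sname in names(subsets)) {
    acc <- question_accuracy(records, condition = subsets[[sname]])
    for (dem in c("education_level", "language_level")) {
      res <- tryCatch(pearson_one_tailed(acc[[dem]], acc$accuracy),
                      error = function(e) NULL)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        subset = sname, demographic = dem,
        r = if (is.null(res)) NA_real_ else res$r,
        p = if (is.null(res)) NA_real_ else res$p,
        n = if (is.null(res)) nrow(acc) else res$n
      )
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "bonferroni") <- bonferroni_threshold(alpha, 4L)
  out
}

#' Accuracy by demographic level or by text
#'
#' Companion summaries to the correlation analysis: mean question accuracy
#' (excluding before-reading items) grouped by an ordinal demographic level,
#' or by text and condition.
#'
#' @param records Filtered response records.
#' @param by `"education_level"`, `"language_level"` or `"text"`.
#' @return A tibble of group means and sizes.
#' @export
accuracy_summary <- function(records, by = c("education_level",
                                             "language_level", "text")) {
  by <- match.arg(by)
  if (by == "text") {
    cols <- c(QUESTION_COLUMNS$while_reading, QUESTION_COLUMNS$after_tf,
              QUESTION_COLUMNS$after_mc)
    acc <- rowMeans(as.matrix(records[, cols]), na.rm = TRUE)
    key <- interaction(records$text_id, records$condition, drop = TRUE)
    agg <- tapply(acc, key, mean)
    ns <- tapply(acc, key, length)
    parts <- strsplit(names(agg), ".", fixed = TRUE)
    return(tibble::tibble(
      text_id = vapply(parts, `[[`, character(1), 1L),
      condition = vapply(parts, `[[`, character(1), 2L),
      accuracy = as.numeric(agg), n = as.integer(ns)))
  }
  acc <- question_accuracy(records)
  agg <- tapply(acc$accuracy, acc[[by]], mean)
  ns <- tapply(acc$accuracy, acc[[by]], length)
  tibble::tibble(level = as.numeric(names(agg)),
                 accuracy = as.numeric(agg), n = as.integer(ns))
}
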