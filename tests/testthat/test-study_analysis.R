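toy_records <- function(n_per_cond = 6, value_orig = 1:6, value_simp = 1:6) {
  tibble::tibble(
    participant_id = sprintf("P%02d", seq_len(2 * n_per_cond)),
    text_id = "asthma",
    condition = rep(c("ORIGINAL", "SIMPLIFIED"), each = n_per_cond),
    reading_seconds = 120,
    likert = c(value_orig, value_simp)
  )
}

test_that("reading-time filtering is per record with a strict <60 cutoff", {
  rec <- tibble::tibble(participant_id = c("P01", "P01", "P02", "P03"),
                        reading_seconds = c(59, 60, 300, NA))
  out <- filter_responses(rec)
  expect_equal(nrow(out$excluded), 1L)
  expect_equal(out$excluded$reading_seconds, 59)
  # 60 s exactly is retained; the participant's other record is untouched
  expect_true(60 %in% out$retained$reading_seconds)
  # missing timing is flagged, not dropped
  expect_true(any(out$retained$flag_missing_timing))
  expect_equal(nrow(out$retained), 3L)
  # retained rows are unaltered apart from the flag column
  expect_equal(out$retained[, names(rec)], rec[c(2, 3, 4), ])

  all_slow <- filter_responses(tibble::tibble(reading_seconds = c(61, 200)))
  expect_equal(nrow(all_slow$excluded), 0L)
})

test_that("one-way ANOVA matches the hand decomposition and aov", {
  # identical groups: no between-group variance at all
  same <- one_way_anova(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(same$F, 0)
  expect_equal(same$p, 1)

  res <- one_way_anova(c(1, 2, 3, 2, 3, 4), rep(c("a", "b"), each = 3))
  expect_equal(res$F, 1.5)            # SSB 1.5, SSW 4, df 1 and 4
  expect_equal(res$df_between, 1L)
  expect_equal(res$df_within, 4L)
  oracle <- summary(stats::aov(v ~ g, data.frame(
    v = c(1, 2, 3, 2, 3, 4), g = rep(c("a", "b"), each = 3))))[[1]]
  expect_equal(res$F, oracle[["F value"]][1], tolerance = 1e-12)
  expect_equal(res$p, oracle[["Pr(>F)"]][1], tolerance = 1e-12)

  # degenerate: zero within-group variance but distinct means
  degen <- one_way_anova(c(1, 1, 2, 2), rep(c("a", "b"), each = 2))
  expect_equal(degen$F, Inf)
  expect_equal(degen$p, 0)
  expect_error(one_way_anova(1:3, c("a", "a", "b")), "2 groups")
})

test_that("two-group ANOVA equals the squared pooled t statistic", {
  set.seed(11)
  for (trial in 1:20) {
    x <- rnorm(sample(5:20, 1))
    y <- rnorm(sample(5:20, 1), mean = runif(1, -1, 1))
    res <- one_way_anova(c(x, y), rep(c("x", "y"), c(length(x), length(y))))
    tt <- stats::t.test(x, y, var.equal = TRUE)
    expect_equal(res$F, unname(tt$statistic)^2, tolerance = 1e-9)
    expect_equal(res$p, tt$p.value, tolerance = 1e-9)
  }
})

test_that("one-tailed Pearson matches hand values and cor.test", {
  perfect <- pearson_one_tailed(1:5, 1:5)
  expect_equal(perfect$r, 1)
  expect_equal(perfect$p, 0)

  res <- pearson_one_tailed(c(1, 2, 3), c(1, 2, 4))
  expect_equal(res$r, 3 / sqrt(2 * 14 / 3), tolerance = 1e-12)  # 0.9820
  oracle <- stats::cor.test(c(1, 2, 3), c(1, 2, 4),
                            alternative = "greater")
  expect_equal(res$r, unname(oracle$estimate), tolerance = 1e-12)
  expect_equal(res$p, oracle$p.value, tolerance = 1e-12)

  set.seed(5)
  for (trial in 1:10) {
    x <- rnorm(sample(5:30, 1))
    y <- rnorm(length(x))
    mine <- pearson_one_tailed(x, y)
    ref <- stats::cor.test(x, y, alternative = "greater")
    expect_equal(mine$p, ref$p.value, tolerance = 1e-9)
  }
  expect_error(pearson_one_tailed(c(1, 1, 1), 1:3), "variance")
  expect_error(pearson_one_tailed(1:2, 1:2), "n >= 3")
})

test_that("Bonferroni threshold is alpha over m", {
  expect_equal(bonferroni_threshold(0.05, 4), 0.0125)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.01, 5), 0.002)
  expect_error(bonferroni_threshold(1.2, 4))
})

test_that("report rows carry condition means, SDs, F and p per measure", {
  resp <- make_responses(synthetic_config(seed = 21))
  rep <- build_report(resp)
  # layout: Likert, 5+5 TF, 2 while, 4 MC, recall metrics, expert, ROUGE
  expect_equal(rep$column[1], "likert")
  expect_equal(sum(grepl("^tf_", rep$column)), 10L)
  expect_equal(sum(grepl("^mc_", rep$column)), 6L)
  expect_equal(sum(grepl("^rouge_", rep$column)), 9L)
  expect_equal(nrow(rep), 34L)   # Likert + 16 questions + 17 recall measures
  # report means are exactly the condition-wise sample means (percent scale
  # for binary items)
  for (col in c("likert", "tf_after_5", "rouge_1_recall")) {
    row <- rep[rep$column == col, ]
    scale <- if (col == "tf_after_5") 100 else 1
    expect_equal(row$mean_original,
                 mean(resp[[col]][resp$condition == "ORIGINAL"]) * scale,
                 tolerance = 1e-12)
    expect_equal(row$sd_simplified,
                 sd(resp[[col]][resp$condition == "SIMPLIFIED"]) * scale,
                 tolerance = 1e-12)
    aovr <- one_way_anova(resp[[col]], resp$condition)
    expect_equal(row$F, aovr$F, tolerance = 1e-12)
    expect_equal(row$p, aovr$p, tolerance = 1e-12)
  }
})

test_that("identical conditions give all-zero F rows; empty cells flag", {
  rec <- toy_records()                         # mirrored values
  rep <- build_report(rec)
  lik <- rep[rep$column == "likert", ]
  expect_equal(lik$F, 0)
  expect_equal(lik$p, 1)
  expect_true(all(rep$flag[rep$column != "likert"] == "missing_column"))

  only_orig <- rec[rec$condition == "ORIGINAL", ]
  rep2 <- build_report(only_orig)
  expect_equal(rep2$flag[rep2$column == "likert"], "empty_condition_cell")
  expect_true(is.na(rep2$F[rep2$column == "likert"]))
})

test_that("question accuracy excludes before-reading items", {
  base <- as.list(stats::setNames(rep(1, 16),
                                  unlist(simpletext:::QUESTION_COLUMNS)))
  base[paste0("tf_before_", 1:5)] <- 0        # wrong before, right after
  rec <- tibble::as_tibble(c(list(participant_id = "P01",
                                  condition = "ORIGINAL"), base))
  acc <- question_accuracy(rec)
  expect_equal(acc$accuracy, 1)               # before-reading items ignored
  acc_mc <- question_accuracy(rec, mc_only = TRUE)
  expect_equal(acc_mc$accuracy, 1)
})

test_that("demographic correlations cover subsets with Bonferroni level", {
  resp <- make_responses(synthetic_config(seed = 31))
  out <- demographic_correlations(filter_responses(resp)$retained)
  expect_equal(nrow(out), 6L)
  expect_setequal(unique(out$subset), c("overall", "original", "simplified"))
  expect_equal(attr(out, "bonferroni"), 0.0125)
  expect_true(all(out$p >= 0 & out$p <= 1, na.rm = TRUE))

  by_edu <- accuracy_summary(filter_responses(resp)$retained,
                             "education_level")
  expect_true(all(by_edu$accuracy >= 0 & by_edu$accuracy <= 1))
  by_text <- accuracy_summary(filter_responses(resp)$retained, "text")
  expect_setequal(unique(by_text$text_id),
                  c("asthma", "cirrhosis", "pemphigus", "polycythemia"))
})
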