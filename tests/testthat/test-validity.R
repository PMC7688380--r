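test_that("exact binomial intervals match the reference implementation", {
  # binom.test's interval is the Clopper-Pearson interval: use it as an
  # independent oracle across a grid of counts
  for (n in c(10, 21, 67, 88)) {
    for (x in unique(c(0, 1, floor(n / 3), n - 1, n))) {
      got <- clopper_pearson_ci(x, n)
      ref <- stats::binom.test(x, n)$conf.int
      expect_equal(unname(got), as.numeric(ref), tolerance = 1e-12)
    }
  }
  # closed-form upper bound at zero successes
  expect_equal(unname(clopper_pearson_ci(0, 10)),
               c(0, 1 - 0.025^(1 / 10)))
  expect_equal(unname(clopper_pearson_ci(10, 10))[2], 1)
  expect_error(clopper_pearson_ci(11, 10))
})

test_that("diagnostic metrics and intervals follow the 2x2 table", {
  dm <- diagnostic_metrics(confusion_table(64, 3, 7, 14))
  est <- stats::setNames(dm$estimate, dm$metric)
  expect_equal(unname(est), c(64 / 67, 14 / 21, 64 / 71, 14 / 17))
  expect_true(all(dm$lower <= dm$estimate & dm$estimate <= dm$upper))
  expect_true(all(dm$lower >= 0 & dm$upper <= 1))

  perfect <- diagnostic_metrics(confusion_table(1, 0, 0, 1))
  expect_equal(perfect$estimate, rep(1, 4))
  degen <- diagnostic_metrics(confusion_table(0, 5, 0, 5))
  expect_equal(degen$estimate[degen$metric == "sensitivity"], 0)
  expect_equal(degen$estimate[degen$metric == "npv"], 0.5)
  # no screen positives: PPV undefined and flagged
  expect_true(is.na(degen$estimate[degen$metric == "ppv"]))
})

test_that("confusion tables cross-tabulate records against the gold standard", {
  allpos <- data.frame(subject_id = 1:3, scale_diff = c(6, 9, 21),
                       gold_positive = TRUE)
  tab <- confusion_from_records(allpos, 5)
  expect_equal(unlist(tab[c("tp", "fn", "fp", "tn")]),
               c(tp = 3L, fn = 0L, fp = 0L, tn = 0L))
  expect_error(confusion_from_records(allpos[0, ], 5), "no records")
  miss <- allpos; miss$gold_positive[2] <- NA
  expect_error(confusion_from_records(miss, 5), "2")

  # independent tally oracle on a simulated cohort
  co <- generate_cohort(cohort_config(n = 100, seed = 12))
  res <- run_screening(co, cutoffs = 5, seed = 12)
  inc <- !res$excluded
  tab <- confusion_from_records(res, 6)
  expect_equal(tab$tp, sum(res$scale_diff[inc] >= 6 & res$gold_positive[inc]))
  expect_equal(tab$fn, sum(res$scale_diff[inc] < 6 & res$gold_positive[inc]))
  expect_equal(tab$fp, sum(res$scale_diff[inc] >= 6 & !res$gold_positive[inc]))
  expect_equal(tab$tn, sum(res$scale_diff[inc] < 6 & !res$gold_positive[inc]))
})

test_that("Fisher-z intervals reproduce and shrink with sample size", {
  ci <- pearson_r_with_ci(r = 0.88, n = 88)
  expect_equal(round(ci$lower, 2), 0.82)
  expect_equal(round(ci$upper, 2), 0.92)
  wide <- pearson_r_with_ci(r = 0.88, n = 88)
  narrow <- pearson_r_with_ci(r = 0.88, n = 352)
  expect_lt(narrow$upper - narrow$lower, wide$upper - wide$lower)

  # data entry point against the reference implementation
  set.seed(3)
  x <- rnorm(60); y <- 0.7 * x + rnorm(60)
  got <- pearson_r_with_ci(x, y)
  ref <- stats::cor.test(x, y)
  expect_equal(got$r, unname(ref$estimate))
  expect_equal(c(got$lower, got$upper), as.numeric(ref$conf.int),
               tolerance = 1e-6)

  expect_true(pearson_r_with_ci(1:10, 2 * (1:10) + 3)$degenerate)
  set.seed(4)
  noise <- pearson_r_with_ci(rnorm(1000), rnorm(1000))
  expect_lt(abs(noise$r), 0.1)
  expect_true(noise$lower < 0 && noise$upper > 0)
  expect_error(pearson_r_with_ci(1:3, 1:3), "at least 4")
  expect_error(pearson_r_with_ci(rep(1, 10), rnorm(10)), "variance")
})

test_that("one-way ANOVA matches hand-computed sums of squares", {
  g <- list(c(12, 15, 14, 11), c(20, 22, 19, 25), c(14, 17, 16, 15))
  got <- anova_oneway(g)
  # independent oracle: explicit between/within sums of squares
  y <- unlist(g); k <- length(g); n <- length(y)
  means <- sapply(g, mean)
  ssb <- sum(sapply(g, length) * (means - mean(y))^2)
  ssw <- sum(unlist(lapply(g, function(v) (v - mean(v))^2)))
  f_ref <- (ssb / (k - 1)) / (ssw / (n - k))
  expect_equal(got$F, f_ref, tolerance = 1e-12)
  expect_equal(got$p, stats::pf(f_ref, k - 1, n - k, lower.tail = FALSE))

  same <- anova_oneway(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(same$F, 0)
  expect_equal(same$p, 1)
  sep <- anova_oneway(list(rnorm(10, 0, 0.1), rnorm(10, 100, 0.1)))
  expect_lt(sep$p, 0.001)
  expect_error(anova_oneway(list(1:3)), "2")
})

test_that("integer 2x2 tables are reconstructed uniquely from printed percentages", {
  t5 <- reconstruct_counts(95.5, 66.7, 90.1, 82.3, 88)
  expect_equal(unlist(t5[c("tp", "fn", "fp", "tn")]),
               c(tp = 64L, fn = 3L, fp = 7L, tn = 14L))
  t6 <- reconstruct_counts(92.5, 85.7, 95.4, 78.3, 88)
  expect_equal(unlist(t6[c("tp", "fn", "fp", "tn")]),
               c(tp = 62L, fn = 5L, fp = 3L, tn = 18L))
  t7 <- reconstruct_counts(91.0, 90.5, 96.8, 76.0, 88)
  expect_equal(unlist(t7[c("tp", "fn", "fp", "tn")]),
               c(tp = 61L, fn = 6L, fp = 2L, tn = 19L))
  expect_error(reconstruct_counts(99.9, 1.1, 50.0, 50.0, 88),
               "no integer table")

  # round trip: metrics of the reconstructed table re-match the printing
  dm <- diagnostic_metrics(t5)
  printed <- c(95.5, 66.7, 90.1, 82.3)
  roundings <- cbind(floor(dm$estimate * 1000 + 0.5) / 10,
                     floor(dm$estimate * 1000) / 10)
  expect_true(all(printed == roundings[, 1] | printed == roundings[, 2]))
})
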