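test_that("cohort generation is reproducible and seed-sensitive", {
  a <- generate_cohort(cohort_config(n = 40, seed = 6))
  b <- generate_cohort(cohort_config(n = 40, seed = 6))
  expect_identical(a$subjects, b$subjects)
  c2 <- generate_cohort(cohort_config(n = 40, seed = 7))
  expect_false(identical(a$subjects, c2$subjects))
  # generation leaves the ambient RNG stream untouched
  set.seed(55); ref <- runif(2)
  set.seed(55); invisible(generate_cohort(cohort_config(n = 10, seed = 1)))
  expect_identical(runif(2), ref)
})

test_that("stratified assignment hits the study margins exactly at n = 88", {
  co <- generate_cohort(cohort_config(seed = 2))
  subj <- co$subjects
  expect_length(subj, 88)
  sex <- vapply(subj, `[[`, "", "sex")
  expect_equal(sum(sex == "female"), 44L)
  grades <- vapply(subj, `[[`, 1L, "grade")
  expect_equal(as.integer(table(factor(grades, levels = 1:5))),
               c(7L, 8L, 43L, 16L, 14L))
  expect_equal(sum(vapply(subj, `[[`, TRUE, "gold_positive")), 67L)
})

test_that("sampled impaired-ear PTA always lies inside its drawn grade interval", {
  cfg <- cohort_config(n = 200, seed = 9)
  co <- generate_cohort(cfg)
  for (s in co$subjects) {
    iv <- cfg$grade_intervals[s$grade, ]
    expect_gte(s$pta_impaired_true, iv[1])
    expect_lte(s$pta_impaired_true, iv[2])
    # impaired-by-construction ear really is the worse one
    expect_gte(s$pta_impaired_true, s$pta_contra_true)
    # and the label matches the audiogram-level gold standard
    expect_equal(s$gold_positive,
                 gold_standard_ssnhl(s$pta_impaired_true, s$pta_contra_true))
  }
  ages <- vapply(co$subjects, `[[`, 1, "age")
  expect_true(all(ages >= 18 & ages <= 90))
})

test_that("cohort summaries are consistent with downstream tallies", {
  co <- generate_cohort(cohort_config(n = 88, seed = 4))
  res <- run_screening(co, cutoffs = 5, seed = 4)
  tab <- confusion_from_records(res, 5)
  inc <- !res$excluded
  expect_equal(tab$tp + tab$fn, sum(res$gold_positive[inc]))
  truth <- vapply(co$subjects, `[[`, TRUE, "gold_positive")
  expect_equal(sum(truth), 67L)
  # the exam-based gold call equals the truth label whenever the true
  # interaural difference clears the 30-dB boundary by more than the
  # 5-dB grid rounding on each ear
  true_diff <- vapply(co$subjects,
                      function(s) s$pta_impaired_true - s$pta_contra_true, 1)
  clear <- abs(true_diff - 30) > 10
  expect_equal(res$gold_positive[clear], truth[clear])
  sm <- summarize_cohort(co, screening = res)
  expect_equal(sm$value[sm$variable == "female"], 50)
  expect_equal(sum(sm$spread[grepl("^grade_", sm$variable)]), 88)
  pta_mean <- sm$value[sm$variable == "pta_worst_ear_db"]
  expect_gt(pta_mean, 55); expect_lt(pta_mean, 75)
  expect_true(all(c("scale_worst_ear", "scale_difference") %in% sm$variable))
})

test_that("degenerate and invalid configurations are rejected", {
  expect_error(cohort_config(n = 1), "at least 2")
  expect_error(cohort_config(grade_mix = c(0.5, 0.5, 0, 0, 0.5)), "sum to 1")
  expect_error(cohort_config(grade_intervals = rbind(c(0, 25), c(45, 25),
                                                     c(45, 75), c(75, 90),
                                                     c(90, 120))),
               "non-empty")
})
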