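test_that("triage groups by the worse ear and refers on scale or asymmetry", {
  t1 <- triage(12, 6)
  expect_equal(as.character(t1$group), ">S10")
  expect_true(t1$referred)
  t2 <- triage(8, 8)
  expect_equal(as.character(t2$group), "S6-S10")
  expect_false(t2$referred)
  # the 5-scale difference cutoff is inclusive
  t3 <- triage(9, 4)
  expect_true(t3$referred)
  expect_false(triage(8, 4)$referred)
  expect_equal(as.character(triage(4, 3)$group), "<=S5")
  expect_equal(as.character(triage(NO_RESPONSE, 4)$group), ">S10")
})

test_that("screen and gold-standard calls use inclusive cutoffs", {
  expect_true(classify_ssnhl_by_scale(5, 5))
  expect_false(classify_ssnhl_by_scale(4, 5))
  expect_true(classify_ssnhl_by_scale(9, 7))
  expect_true(gold_standard_ssnhl(70, 40))
  expect_false(gold_standard_ssnhl(69.9, 40))
  expect_true(gold_standard_ssnhl(62.6, 15))  # 47.6-dB difference regime
})

test_that("a single impaired deterministic subject flows through the pipeline", {
  ag <- flat_ag(c(15, 15, 15, 15), c(85, 85, 85, 85))
  res <- run_screening(list(listener(ag, deterministic = TRUE)),
                       cutoffs = 5:7)
  expect_equal(nrow(res), 1L)
  expect_equal(res$scale_right, 17L)
  expect_equal(res$scale_left, 3L)
  expect_equal(res$impaired_ear, "right")
  expect_equal(res$scale_diff, 14L)
  expect_true(res$referred)
  expect_true(res$gold_positive)
  expect_true(res$screen_cut5 && res$screen_cut6 && res$screen_cut7)
  # symmetric normal hearing: low group, no referral, all negative
  sym <- run_screening(list(det_listener(15)), cutoffs = 5)
  expect_equal(sym$triage_group, "<=S5")
  expect_false(sym$referred)
  expect_false(sym$gold_positive)
  expect_false(sym$screen_cut5)
})

test_that("screen positives at the referral cutoff are always referred", {
  co <- generate_cohort(cohort_config(n = 120, seed = 5))
  res <- run_screening(co, cutoffs = 5:7, seed = 5)
  inc <- !res$excluded
  expect_true(all(res$referred[inc & res$screen_cut5]))
  expect_true(all(res$referred[inc & res$screen_cut7]))
})

test_that("raising the cutoff never creates a positive, and validity is monotone", {
  co <- generate_cohort(cohort_config(n = 150, seed = 8))
  res <- run_screening(co, cutoffs = 5:7, seed = 8)
  inc <- !res$excluded
  expect_true(all(res$screen_cut6[inc] <= res$screen_cut5[inc]))
  expect_true(all(res$screen_cut7[inc] <= res$screen_cut6[inc]))
  vt <- validity_table(res, cutoffs = 5:7)
  expect_true(all(diff(vt$sensitivity) <= 0))
  expect_true(all(diff(vt$specificity) >= 0))
})

test_that("subjects labelled with bilateral or conductive loss are excluded", {
  good <- list(subject_id = 1, age = 50, sex = "female",
               audiogram = flat_ag(15, 85),
               bilateral_loss = FALSE, conductive_loss = FALSE)
  bil <- utils::modifyList(good, list(subject_id = 2, bilateral_loss = TRUE))
  con <- utils::modifyList(good, list(subject_id = 3, conductive_loss = TRUE))
  res <- run_screening(list(good, bil, con), cutoffs = 5)
  expect_equal(res$excluded, c(FALSE, TRUE, TRUE))
  tab <- confusion_from_records(res, 5)
  expect_equal(attr(tab, "n"), 1L)
})

test_that("per-subject failures are flagged and the run continues", {
  ok <- det_listener(c(15, 15, 15, 15), c(85, 85, 85, 85))
  # missing HST frequencies make this subject fail
  broken <- list(subject_id = 2, age = 40, sex = "male",
                 audiogram = audiogram(left = 20, right = 20,
                                       frequencies = 1000),
                 bilateral_loss = FALSE, conductive_loss = FALSE)
  res <- run_screening(list(ok, broken), cutoffs = 5)
  expect_equal(res$excluded, c(FALSE, TRUE))
  expect_match(res$exclusion_reason[2], "failed")
  expect_true(res$screen_cut5[1])
})
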