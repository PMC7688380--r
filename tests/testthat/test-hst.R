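test_that("the ambient-noise gate requires strictly less than the limit", {
  expect_true(ambient_noise_gate(49.9))
  expect_false(ambient_noise_gate(50))
  expect_true(ambient_noise_gate(30))
  expect_error(ambient_noise_gate(-1), "non-negative")
  expect_error(run_hst(det_listener(20), "left", ambient_dba = 55),
               "ambient noise gate")
})

test_that("the deterministic scale search finds the minimum all-correct scale", {
  expect_equal(run_hst(det_listener(20), "left")$min_audible_scale, 4L)
  l <- listener(flat_ag(20, c(40, 83, 60, 55)), deterministic = TRUE)
  expect_equal(run_hst(l, "right")$min_audible_scale, 17L)
  # any threshold above 100 dB HL exceeds S20
  l2 <- listener(flat_ag(20, c(40, 101, 60, 55)), deterministic = TRUE)
  r2 <- run_hst(l2, "right", config = hst_config(max_presentations = 200))
  expect_equal(r2$min_audible_scale, NO_RESPONSE)
  expect_true(r2$valid)
})

test_that("the scale search matches the brute-force oracle on random audiograms", {
  set.seed(42)
  for (i in 1:200) {
    ag <- random_audiogram()
    l <- listener(ag, deterministic = TRUE)
    ear <- sample(c("left", "right"), 1)
    got <- run_hst(l, ear,
                   config = hst_config(max_presentations = 300))
    expect_true(got$valid)
    expect_equal(got$min_audible_scale, brute_force_hst(ag, ear))
  }
})

test_that("the deterministic result does not depend on the start scale", {
  ag <- flat_ag(c(40, 83, 60, 55))
  l <- listener(ag, deterministic = TRUE)
  res <- sapply(1:20, function(s) {
    run_hst(l, "left", hst_config(start_scale = s,
                                  max_presentations = 300))$min_audible_scale
  })
  expect_true(all(res == brute_force_hst(ag, "left")))
})

test_that("trial blocks present frequencies in order and stop at the first miss", {
  cfg <- hst_config()
  l <- listener(flat_ag(c(40, 83, 60, 55)), deterministic = TRUE)
  log <- run_hst(l, "left", cfg)$trial_log
  expect_true(all(log$level_dbhl == 5 * log$scale))
  blocks <- split(log, cumsum(c(1, diff(log$scale) != 0)))
  for (b in blocks) {
    k <- nrow(b)
    expect_equal(b$freq_hz, cfg$freq_order[seq_len(k)])
    # only the last presentation of a block may be a miss
    if (k > 1) expect_true(all(b$response[seq_len(k - 1)]))
  }
})

test_that("both-ear runs designate the worse ear and difference", {
  l <- listener(flat_ag(c(20, 20, 15, 10), c(40, 83, 60, 55)),
                deterministic = TRUE)
  pair <- hst_both_ears(l)
  expect_equal(pair$right$min_audible_scale, 17L)
  expect_equal(pair$left$min_audible_scale, 4L)
  expect_equal(pair$impaired_ear, "right")
  expect_equal(pair$scale_diff, 13L)
  # identical ears: zero difference, right by tie-break
  sym <- hst_both_ears(det_listener(20))
  expect_equal(sym$scale_diff, 0L)
  expect_equal(sym$impaired_ear, "right")
  # no-response ear enters as scale 21
  nr <- listener(flat_ag(c(110, 110, 110, 110), c(75, 75, 75, 75)),
                 deterministic = TRUE)
  pnr <- hst_both_ears(nr, config = hst_config(max_presentations = 200))
  expect_equal(pnr$left$min_audible_scale, NO_RESPONSE)
  expect_equal(pnr$right$min_audible_scale, 15L)
  expect_equal(pnr$scale_diff, 6L)
})

test_that("stochastic runs stay within one scale of the deterministic result", {
  # thresholds 10 dB away from every scale boundary would need multiples of
  # 5 offset by 10; use mid-scale thresholds (2-3 dB from the boundary is
  # the grid's maximum clearance, so allow the +-1 scale band)
  ag <- flat_ag(c(37, 42, 48, 53))
  want <- brute_force_hst(ag, "left")
  l <- listener(ag, slope_db = 3, guess_rate = 0.02, lapse_rate = 0.02,
                seed = 31)
  res <- replicate(500, {
    r <- run_hst(l, "left", hst_config(max_presentations = 200))
    if (r$valid) r$min_audible_scale else NA_integer_
  })
  res <- res[!is.na(res)]
  expect_gt(length(res), 450)
  expect_lt(abs(mean(res) - want), 1)
  expect_gt(mean(abs(res - want) <= 1), 0.9)
})

test_that("exceeding the presentation cap aborts rather than guesses", {
  l <- det_listener(c(40, 83, 60, 55))
  r <- run_hst(l, "left", hst_config(max_presentations = 5))
  expect_false(r$valid)
  expect_true(is.na(r$min_audible_scale))
  expect_match(r$abort_reason, "max_presentations")
})

test_that("confirmation repeats do not change a deterministic result", {
  l <- det_listener(c(40, 83, 60, 55))
  r <- run_hst(l, "left", hst_config(confirm_repeats = 2,
                                     max_presentations = 300))
  expect_equal(r$min_audible_scale, 17L)
})

test_that("the configuration rejects invalid grids", {
  expect_error(hst_config(start_scale = 0), "1..20")
  expect_error(hst_config(freq_order = c(1000, 2000, 4000, 8000)),
               "permutation")
})
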