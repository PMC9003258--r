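test_that("subject draws respect class truncation bounds and stage lookup", {
  cfg <- simulator_config(seed = 11)
  subs <- lapply(1:60, function(i) sample_subject(cfg, i))
  tt <- vapply(subs, `[[`, 0, "tolerance_time")
  cl <- vapply(subs, `[[`, "", "tolerance_class")
  expect_true(all(tt[cl == "LT"] >= 601 & tt[cl == "LT"] <= 1499))
  expect_true(all(tt[cl == "HT"] >= 1501 & tt[cl == "HT"] <= 2700))
  # lbnp_at_hd is the active schedule level at the tolerance time
  for (s in subs)
    expect_equal(s$lbnp_at_hd,
                 protocol_lbnp(cfg$schedule,
                               min(s$tolerance_time, 2700 - 1e-9)))
  # worked stage-table examples: 1286 s -> 60 mmHg, 1838 s -> 80 mmHg
  expect_equal(protocol_lbnp(cfg$schedule, 1286), 60)
  expect_equal(protocol_lbnp(cfg$schedule, 1838), 80)
})

test_that("draws are deterministic and independent of cohort size", {
  cfg <- simulator_config(seed = 7)
  a <- sample_subject(cfg, 5)
  b <- sample_subject(cfg, 5)
  expect_identical(a, b)
  co_small <- generate_cohort(simulator_config(n_subjects = 5, seed = 7),
                              waveforms = FALSE)
  co_big <- generate_cohort(simulator_config(n_subjects = 10, seed = 7),
                            waveforms = FALSE)
  expect_identical(co_small$profiles, co_big$profiles[1:5, ])
})

test_that("moment matching removes the truncation bias of class means", {
  cfg <- simulator_config(seed = 1)
  # the solver's own report
  expect_equal(cfg$lt_draw$achieved_mean, 1286, tolerance = 1e-3)
  expect_equal(cfg$ht_draw$achieved_mean, 1838, tolerance = 1e-3)
  expect_equal(cfg$ht_draw$achieved_sd, 262, tolerance = 1e-2)
  # Monte Carlo confirmation against the sampler actually used
  set.seed(4)
  x <- crwave:::.rtruncnorm(40000, cfg$ht_draw$mu, cfg$ht_draw$sigma,
                            1501, 2700)
  expect_equal(mean(x), 1838, tolerance = 5)
  expect_equal(sd(x), 262, tolerance = 5)
  y <- crwave:::.rtruncnorm(40000, cfg$lt_draw$mu, cfg$lt_draw$sigma,
                            601, 1499)
  expect_equal(mean(y), 1286, tolerance = 5)
})

test_that("cohort class frequency follows the configured Bernoulli", {
  co <- generate_cohort(simulator_config(seed = 42), waveforms = FALSE)
  expect_equal(nrow(co$profiles), 191)
  n_lt <- sum(co$profiles$tolerance_class == "LT")
  # E = 60, binomial sd ~ 6.4; allow 3 sd
  expect_gt(n_lt, 60 - 3 * 6.4)
  expect_lt(n_lt, 60 + 3 * 6.4)
  expect_true(all(co$profiles$tolerance_class ==
                    classify_tolerance(co$profiles$tolerance_time)))
})

test_that("waveform obeys the length identity and pressure positivity", {
  w <- demo_record()
  s <- demo_subject()
  expect_equal(length(w$pressure), round(s$tolerance_time * 500))
  expect_true(all(w$pressure > 0))
  expect_equal(w$sampling_rate, 500)
  expect_equal(w$decomp_time, s$tolerance_time)
})

test_that("noise-free baseline beats are periodic and start near SBP0", {
  w <- demo_record_clean()
  on <- w$beat_onsets
  base <- on[on < 60]
  expect_gt(length(base), 50)
  expect_lt(sd(diff(base)), 1e-9)              # identical intervals
  # per-beat peaks in the baseline minute agree closely
  peaks <- vapply(seq_len(length(base) - 1), function(j) {
    i0 <- floor(base[j] * 500) + 1; i1 <- floor(base[j + 1] * 500)
    max(w$pressure[i0:i1])
  }, 0)
  expect_lt(diff(range(peaks)), 0.05)
  expect_lt(abs(peaks[1] - 120), 5)            # within 5 mmHg of SBP0
})

test_that("morphology degrades with depletion: HR rises, SBP collapses", {
  w <- demo_record_clean()
  s <- demo_subject()
  on <- w$beat_onsets
  hr_first <- sum(on < 60)
  hr_last <- sum(on > s$tolerance_time - 60)
  expect_gt(hr_last, hr_first)
  expect_lt(final_beat_sbp(w), 80)
  expect_lt(final_beat_sbp(demo_record()), 80)  # with noise too
})

test_that("invalid configurations are rejected", {
  expect_error(simulator_config(ht_tolerance_sd = -1), "configuration")
  expect_error(simulator_config(noise_sd = -2), "configuration")
  expect_error(simulator_config(p_high_tolerance = 1.2), "configuration")
  expect_error(simulator_config(sbp_end = 90), "configuration")
})
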