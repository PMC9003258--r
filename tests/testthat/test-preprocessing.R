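test_that("truncation keeps [start, end) and never alters values", {
  w <- demo_record()
  full <- truncate_record(w, w$start_time, w$decomp_time)
  expect_equal(full$pressure, w$pressure)
  t300 <- truncate_record(w, 0, 300)
  expect_equal(length(t300$pressure), 150000)  # 300 s x 500 samples/s
  expect_identical(t300$pressure, w$pressure[1:150000])
  expect_error(truncate_record(w, 10, 10), "empty")
  expect_error(truncate_record(w, 0, w$decomp_time + 5), "beyond")
})

test_that("resampler matches a brute-force interpolation oracle", {
  # 10 s of a 1 Hz sinusoid at 500 samples/s
  t_in <- seq(0, 10 - 1 / 500, by = 1 / 500)
  x <- 100 + 20 * sin(2 * pi * t_in)
  rec <- waveform_record("sin", x, 500)
  out <- resample_100hz(rec)
  expect_equal(out$sampling_rate, 100)
  t_out <- (seq_along(out$pressure) - 1) / 100
  # independently coded pointwise linear interpolation
  oracle <- vapply(t_out, function(t) {
    i <- floor(t * 500) + 1
    if (i >= length(x)) return(x[length(x)])
    w <- (t - t_in[i]) / (1 / 500)
    (1 - w) * x[i] + w * x[i + 1]
  }, 0)
  expect_equal(out$pressure, oracle, tolerance = 1e-12)
  # random record property: oracle agreement at machine precision
  set.seed(8)
  y <- cumsum(rnorm(5000))
  rec2 <- waveform_record("rw", y, 500)
  out2 <- resample_100hz(rec2)
  t2 <- (seq_along(out2$pressure) - 1) / 100
  or2 <- approx((seq_along(y) - 1) / 500, y, xout = pmin(t2, (4999) / 500))$y
  expect_equal(out2$pressure, or2, tolerance = 1e-12)
  # constant input -> constant output
  outc <- resample_100hz(waveform_record("c", rep(80, 1000), 500))
  expect_true(all(outc$pressure == 80))
  # duration preserved to within one input sample period
  expect_lt(abs(record_duration(out2) - record_duration(rec2)), 1 / 500)
})

test_that("min/max normalization attains 0 and 1 and is affine invariant", {
  w <- demo_record()
  n <- normalize_minmax(w)
  expect_equal(min(n$pressure), 0)
  expect_equal(max(n$pressure), 1)
  expect_true(n$normalized)
  # value 110 in a record spanning [60, 160] maps to 0.5
  rec <- waveform_record("r", c(60, 110, 160, 100), 500,
                         decomp_time = 4 / 500)
  expect_equal(normalize_minmax(rec)$pressure[2], 0.5)
  # affine rescaling of the input leaves the output unchanged
  w2 <- w; w2$pressure <- 3.7 * w$pressure + 11
  expect_equal(normalize_minmax(w2)$pressure, n$pressure, tolerance = 1e-12)
  flat <- waveform_record("f", rep(5, 600), 100, decomp_time = 6)
  expect_error(normalize_minmax(flat), "degenerate")
})

test_that("segmentation drops remainders and flags the final segment", {
  mk <- function(dur) waveform_record("x", seq_len(dur * 100), 100,
                                      decomp_time = dur)
  s1500 <- segment_record(mk(1500))
  expect_equal(nrow(s1500$samples), 75)
  expect_equal(ncol(s1500$samples), 2000)
  s1510 <- segment_record(mk(1510))
  expect_equal(nrow(s1510$samples), 75)  # trailing 10 s dropped
  expect_equal(sum(s1510$meta$decomp_flag), 1)
  expect_true(s1510$meta$decomp_flag[75])
  # segments tile the record without overlap
  expect_equal(as.numeric(t(s1500$samples)), seq_len(150000))
  expect_error(segment_record(mk(10)), "shorter")
  expect_error(segment_record(waveform_record("y", 1:5000, 500,
                                              decomp_time = 10)),
               "100 samples")
})

test_that("targets are stepwise, start at 1, end at 0", {
  co <- tiny_cohort()
  sch <- co$config$schedule
  for (i in seq_along(co$subjects)) {
    segs <- preprocess_record(co$records[[i]], co$subjects[[i]], sch)
    tgt <- segs$meta$target
    expect_equal(tgt[1], 1)
    expect_equal(tgt[length(tgt)], 0)
    expect_true(all(diff(tgt) <= 1e-12))
    expect_true(all(tgt >= 0 & tgt <= 1))
    expect_equal(sum(segs$meta$decomp_flag), 1)
    expect_true(all(segs$samples >= 0 & segs$samples <= 1))
    expect_equal(ncol(segs$samples), 2000)
  }
})

test_that("target lookup uses the segment start time", {
  # subject with lbnp_at_hd = 90: a segment starting at 700 s sits in the
  # 30 mmHg stage, so the target is 1 - 30/90
  cfg <- simulator_config(seed = 1)
  hd90 <- NULL
  for (i in 1:400) {
    s <- sample_subject(cfg, i)
    if (s$lbnp_at_hd == 90) { hd90 <- s; break }
  }
  expect_false(is.null(hd90))
  seg <- structure(list(samples = matrix(0.5, 37, 2000),
                        meta = data.frame(subject_id = hd90$subject_id,
                                          segment_index = 1:37,
                                          start_time = seq(0, 720, by = 20),
                                          target = NA_real_,
                                          decomp_flag = c(rep(FALSE, 36),
                                                          TRUE)),
                        seg_seconds = 20, rate = 100),
                   class = "segment_set")
  out <- assign_targets(seg, hd90, stage_schedule())
  expect_equal(out$meta$target[37], 0)  # decomp segment pinned to 0
  expect_equal(out$meta$target[out$meta$start_time == 700],
               1 - 30 / 90)             # 700 s sits in the 30 mmHg stage
  expect_equal(out$meta$target[out$meta$start_time == 500],
               1 - 15 / 90)
})
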