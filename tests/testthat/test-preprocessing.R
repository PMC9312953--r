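test_that("bandpass filter rejects DC and the stopband, passes the band", {
  fs <- 360
  dc <- bandpass_filter(ecg_record(rep(5, 10 * fs)))$samples
  expect_lt(max(abs(dc)), 0.05)

  t <- seq_len(10 * fs)
  mid <- (2 * fs):(8 * fs)
  pass <- bandpass_filter(ecg_record(sin(2 * pi * 10 * t / fs)))$samples
  expect_lt(abs(max(abs(pass[mid])) - 1), 0.05)
  stopb <- bandpass_filter(ecg_record(sin(2 * pi * 170 * t / fs)))$samples
  expect_lt(max(abs(stopb[mid])), 0.10)

  expect_error(bandpass_filter(ecg_record(rnorm(720), fs = 300), high = 160),
               "Nyquist")
})

test_that("max-min normalization and its inverse", {
  r <- normalize_minmax(ecg_record(c(2, 4, 6)))
  expect_equal(r$record$samples, c(0, 0.5, 1))
  expect_equal(r$params$min_value, 2)
  expect_equal(r$params$max_value, 6)

  r01 <- normalize_minmax(ecg_record(c(0, 1)))
  expect_equal(r01$record$samples, c(0, 1))

  x <- rnorm(500) * 7 + 3
  n <- normalize_minmax(ecg_record(x))
  expect_true(all(n$record$samples >= 0 & n$record$samples <= 1))
  expect_equal(denormalize(n$record$samples, n$params), x)
  # order preservation
  expect_identical(order(n$record$samples), order(x))

  expect_error(normalize_minmax(ecg_record(rep(1, 10))), "constant")
})

test_that("R-peak detection recovers truth on clean and noisy records", {
  rec <- generate_ecg(rhythm = clean_rhythm(15L), seed = 2)
  pre <- preprocess_record(rec)
  pk <- detect_r_peaks(pre$record)
  expect_identical(length(pk), length(rec$r_truth))
  expect_true(all(abs(pk - rec$r_truth) <= 2L))
  expect_true(all(diff(pk) >= 72L))

  # 5% noise relative to unit QRS amplitude: sensitivity >= 99%
  noisy <- generate_ecg(
    rhythm = rhythm_params(n_beats = 100L, noise_sd = 0.05,
                           baseline_amp = 0.08),
    seed = 9)
  pren <- preprocess_record(noisy)
  pkn <- detect_r_peaks(pren$record)
  hits <- sum(vapply(noisy$r_truth,
                     function(r) any(abs(pkn - r) <= 10L), logical(1)))
  expect_gte(hits / length(noisy$r_truth), 0.99)

  expect_identical(detect_r_peaks(ecg_record(rep(0, 720))), integer(0))
  expect_error(detect_r_peaks(ecg_record(rnorm(100))), "short")
})

test_that("beat windows are exactly 127 + 192 + 1 samples", {
  rec <- ecg_record(seq_len(1000))
  b <- segment_beats(rec, 501L)
  expect_identical(nrow(b$samples), 320L)
  expect_equal(b$samples[, 1], 374:693)  # 1-based window around r = 501

  whole <- segment_beats(ecg_record(seq_len(320)), 128L)
  expect_equal(whole$samples[, 1], 1:320)

  # too-close-to-start beat skipped, the rest unaffected
  expect_message(b2 <- segment_beats(rec, c(101L, 501L)), "skipped")
  expect_identical(ncol(b2$samples), 1L)
  expect_identical(b2$r_index, 501L)
})

test_that("interval encoding follows the delay/overlap rule", {
  expect_equal(encode_interval(320), data.frame(flag = 0L, magnitude = 0L))
  expect_equal(encode_interval(400), data.frame(flag = 0L, magnitude = 80L))
  expect_equal(encode_interval(286), data.frame(flag = 1L, magnitude = 34L))
  expect_error(encode_interval(320 + 512), "9-bit")
  expect_error(encode_interval(320 - 512), "9-bit")

  expect_identical(decode_interval(data.frame(flag = 0L, magnitude = 0L)), 0L)
  expect_identical(decode_interval(data.frame(flag = 1L, magnitude = 34L)),
                   -34L)
})

test_that("interval code round-trips over every encodable gap", {
  rr <- (320 - 511):(320 + 511)  # all 1023 encodable RR values
  code <- encode_interval(rr)
  expect_identical(decode_interval(code) + 320L, as.integer(rr))
  expect_true(all(code$magnitude >= 0L & code$magnitude <= 511L))
  expect_true(all(code$flag %in% c(0L, 1L)))
})

test_that("first beat of a record gets the null interval", {
  iv <- beat_intervals(c(500L, 820L, 1100L))
  expect_equal(iv$flag, c(0L, 0L, 1L))
  expect_equal(iv$magnitude, c(0L, 0L, 40L))
})
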