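test_that("beat template reduces to the analytic Gaussian sum", {
  morph <- morphology_preset("normal")

  # zero amplitudes give a flat template
  zero <- morph
  zero$wave_amplitudes[] <- c(0, 0, 1e-12, 0, 0)  # R still strictly largest
  expect_equal(generate_beat_template(zero, 320L), rep(0, 320),
               tolerance = 1e-9)

  # a single wave at the R position peaks at exactly 1 and is symmetric
  single <- morphology_params(
    wave_centers = c(-80, -40, 0, 40, 80),
    wave_amplitudes = c(0, 0, 1, 0, 0),
    wave_widths = c(5, 5, 6, 5, 5))
  y <- generate_beat_template(single, length = 257L, r_pos = 129L)
  expect_equal(y[129L], 1)
  expect_equal(y, rev(y))

  # default preset: argmax lands on the declared R position
  y <- generate_beat_template(morph, length = 320L, r_pos = 128L)
  expect_identical(which.max(y), 128L)
  # and equals the direct evaluation of the Gaussian sum
  t_rel <- seq_len(320L) - 128L
  direct <- Reduce(`+`, lapply(c("P", "Q", "R", "S", "T"), function(w)
    morph$wave_amplitudes[[w]] *
      exp(-(t_rel - morph$wave_centers[[w]])^2 /
            (2 * morph$wave_widths[[w]]^2))))
  expect_equal(y, direct)
})

test_that("template errors name a wave that does not fit", {
  morph <- morphology_preset("tall_t")
  expect_error(generate_beat_template(morph, length = 120L, r_pos = 60L),
               "wave")
})

test_that("morphology invariants are enforced", {
  expect_error(morphology_params(c(-60, -12, 0, 12, 75),
                                 c(0.2, -0.1, 0.5, -0.6, 0.3),
                                 c(11, 3, 4, 4, 19)),
               "strictly largest")
  expect_error(morphology_params(c(-60, -12, 0, 12, 75),
                                 c(0.2, -0.1, 1, -0.2, 0.3),
                                 c(11, 3, 0, 4, 19)),
               "widths")
  expect_error(rhythm_params(rr_mean = 30, rr_sd = 15), "positive")
  expect_error(rhythm_params(rr_mean = 900), "encodable")
})

test_that("a single clean beat is one quantized template", {
  rec <- generate_ecg(rhythm = clean_rhythm(1L), seed = 11)
  expect_length(rec$r_truth, 1L)
  expect_true(rec$quantized)
  expect_true(all(rec$samples >= 0 & rec$samples <= 2047))
  # the quantized record, mapped back to [0,1], matches the template shape
  tmpl <- generate_beat_template(morphology_preset("normal"))
  span <- (rec$r_truth - 127L):(rec$r_truth + 192L)
  x <- rec$samples[span] / 2047
  expect_gt(stats::cor(x, tmpl), 0.9999)
})

test_that("generation is a pure function of its arguments", {
  a <- generate_ecg(rhythm = rhythm_params(n_beats = 5L), seed = 42)
  b <- generate_ecg(rhythm = rhythm_params(n_beats = 5L), seed = 42)
  expect_identical(a, b)
  c <- generate_ecg(rhythm = rhythm_params(n_beats = 5L), seed = 43)
  expect_false(identical(a$samples, c$samples))
})

test_that("empirical mean RR tracks the requested rhythm", {
  rh <- rhythm_preset("gap", n_beats = 100L)  # mean RR 422.85
  rec <- generate_ecg(rhythm = rh, seed = 7)
  rr <- diff(rec$r_truth)
  expect_lt(abs(mean(rr) - 422.85), 3 * rh$rr_sd / sqrt(99))
})

test_that("quantization respects the ADC bound for every preset", {
  for (p in c("normal", "tall_t", "wide_qrs")) {
    rec <- generate_ecg(morphology_preset(p),
                        rhythm_params(n_beats = 8L), seed = 3)
    expect_true(all(rec$samples >= 0 & rec$samples <= 2^11 - 1))
    expect_true(all(rec$samples == round(rec$samples)))
  }
})

test_that("clean synthetic R truth is recovered by the detector", {
  rec <- generate_ecg(rhythm = clean_rhythm(12L), seed = 5)
  pre <- preprocess_record(rec)
  pk <- detect_r_peaks(pre$record)
  expect_length(pk, length(rec$r_truth))
  expect_true(all(abs(pk - rec$r_truth) <= 2L))
})
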