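test_that("pack layout is flag, 9 magnitude bits MSB-first, 20 code bits", {
  zero <- pack_unit(data.frame(flag = 0L, magnitude = 0L), rep(0L, 20))
  expect_equal(as.integer(zero), rep(0L, 30))

  code <- rbinom(20, 1, 0.5)
  p <- pack_unit(data.frame(flag = 1L, magnitude = 34L), code)
  expect_equal(as.integer(p[1:10]), c(1L, 0L, 0L, 0L, 1L, 0L, 0L, 0L, 1L, 0L))
  expect_equal(as.integer(p[11:30]), code)
})

test_that("pack/unpack is the bit-exact identity on random packs", {
  set.seed(12)
  n <- 10000L
  iv <- data.frame(flag = sample(0:1, n, TRUE),
                   magnitude = sample(0:511, n, TRUE))
  codes <- matrix(sample(0:1, 20 * n, TRUE), 20, n)
  up <- unpack_unit(pack_unit(iv, codes))
  expect_identical(up$interval$flag, iv$flag)
  expect_identical(up$interval$magnitude, iv$magnitude)
  expect_identical(up$code, codes)
})

test_that("stream serialization round-trips through the .becg format", {
  set.seed(13)
  n <- 257L  # odd count exercises the final-byte zero padding
  iv <- data.frame(flag = sample(0:1, n, TRUE),
                   magnitude = sample(0:511, n, TRUE))
  codes <- matrix(sample(0:1, 20 * n, TRUE), 20, n)
  norm <- structure(list(min_value = -2.5, max_value = 7.25),
                    class = "becg_norm")
  s <- becg_stream(iv, codes, fs = 360, resolution_bits = 11L,
                   norm_params = norm)
  path <- tempfile(fileext = ".becg")
  on.exit(unlink(path))
  write_becg(s, path)
  r <- read_becg(path)
  expect_identical(r$intervals$flag, iv$flag)
  expect_identical(r$intervals$magnitude, iv$magnitude)
  expect_identical(r$codes, codes)
  expect_equal(r$fs, 360)
  expect_identical(r$resolution_bits, 11L)
  expect_identical(r$beat_count, n)
  expect_equal(r$norm_params$min_value, -2.5)
  expect_equal(r$norm_params$max_value, 7.25)

  # payload bit budget: 30 bits per beat after the 34-byte header,
  # byte-padded at the end only
  expect_equal(file.size(path) - 34, ceiling(30 * n / 8))
})

test_that("truncated and corrupt streams are rejected", {
  set.seed(14)
  iv <- data.frame(flag = rep(0L, 10), magnitude = rep(3L, 10))
  codes <- matrix(1L, 20, 10)
  s <- becg_stream(iv, codes)
  path <- tempfile(fileext = ".becg")
  on.exit(unlink(path))
  write_becg(s, path)
  raw <- readBin(path, "raw", file.size(path))
  writeBin(raw[1:(length(raw) - 10L)], path)
  expect_error(read_becg(path), "truncated payload")
  writeBin(c(charToRaw("NOPE"), raw[-(1:4)]), path)
  expect_error(read_becg(path), "not a .becg")
})

test_that("stitching obeys the gap/overlap rules and the length law", {
  b1 <- rep(0.2, 320); b2 <- rep(0.6, 320)
  iv0 <- data.frame(flag = c(0L, 0L), magnitude = c(0L, 0L))
  expect_equal(stitch_record(cbind(b1, b2), iv0), c(b1, b2))

  # gap of 3 between 0.2 and 0.6 interpolates 0.3, 0.4, 0.5
  iv3 <- data.frame(flag = c(0L, 0L), magnitude = c(0L, 3L))
  out <- stitch_record(cbind(b1, b2), iv3)
  expect_length(out, 643L)
  expect_equal(out[321:323], c(0.3, 0.4, 0.5))

  # when the two overlapping segments carry equal values, averaging leaves
  # them unchanged (40-periodic beat: previous tail == current head)
  beat <- rep(runif(40), 8)
  ivo <- data.frame(flag = c(0L, 1L), magnitude = c(0L, 40L))
  out2 <- stitch_record(cbind(beat, beat), ivo)
  expect_length(out2, 600L)
  expect_equal(out2[281:320], beat[281:320])

  # overlap averaging is symmetric in the two segments
  a <- runif(320); b <- runif(320)
  o_ab <- stitch_record(cbind(a, b), ivo)
  swap <- c(rev(b), rev(a))  # reversing time swaps previous/current roles
  o_ba <- stitch_record(cbind(rev(b), rev(a)), ivo)
  expect_equal(o_ab[281:320], rev(o_ba[281:320]))

  expect_error(stitch_record(cbind(a, b),
                             data.frame(flag = c(0L, 1L),
                                        magnitude = c(0L, 330L))),
               "whole beat")

  # randomized stitched-length law
  set.seed(15)
  for (i in 1:20) {
    n <- sample(2:8, 1)
    gaps <- sample(-250:400, n - 1L, TRUE)
    iv <- rbind(data.frame(flag = 0L, magnitude = 0L),
                data.frame(flag = as.integer(gaps < 0), magnitude = abs(gaps)))
    beats <- matrix(runif(320 * n), 320, n)
    expect_length(stitch_record(beats, iv), 320L + sum(320L + gaps))
  }
})

test_that("compression emits one 30-bit pack per detected beat", {
  m <- build_bcae(seed = 21)
  rec <- generate_ecg(rhythm = rhythm_params(n_beats = 25L), seed = 21)
  stream <- compress_record(rec, m)
  expect_identical(stream$beat_count, 25L)
  sb <- stream_bits(stream)
  expect_identical(sb$bits_out, 30 * 25)
  expect_identical(sb$bits_in, 320 * 11 * 25)
  expect_equal(sb$cr, 3520 / 30)

  # header-only stream for a record with no beats
  s0 <- compress_record(rec, m, r_indices = integer(0))
  expect_identical(s0$beat_count, 0L)
  r0 <- decompress_stream(s0, m)
  expect_length(r0$samples, 0L)
})

test_that("a compressed stream round-trips to an aligned reconstruction", {
  m <- build_bcae(seed = 22)
  rec <- generate_ecg(rhythm = rhythm_preset("overlap", n_beats = 15L),
                      seed = 22)
  rt <- round_trip_record(rec, m)
  expect_identical(length(rt$reconstructed), length(rt$original))
  gaps <- decode_interval(rt$stream$intervals)
  expect_identical(length(rt$reconstructed),
                   320L + sum(320L + gaps[-1]))

  # unencodable RR raises with the beat index
  rec2 <- generate_ecg(rhythm = rhythm_params(n_beats = 1L), seed = 3)
  rec2$samples <- rep(rec2$samples, 4)
  expect_error(compress_record(rec2, m, r_indices = c(500L, 1400L)),
               "beat 2")
})
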