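test_that("metric formulas match their hand-computed cases", {
  expect_equal(compression_ratio(3520, 30), 117.33, tolerance = 1e-4)
  expect_equal(compression_ratio(100, 100), 1)
  expect_equal(compression_ratio(100, 4), 25)
  expect_error(compression_ratio(10, 0), "positive")

  expect_equal(prd(c(3, 4), c(3, 4)), 0)
  expect_equal(prd(c(3, 4), c(0, 0)), 100)
  expect_equal(prd(c(1, 0), c(0, 0)), 100)
  expect_equal(prd(c(1, 1), c(1, 0)), 100 * sqrt(1 / 2))
  expect_error(prd(c(0, 0), c(1, 1)), "all-zero")

  expect_equal(prdn(c(0, 2), c(0, 2)), 0)
  expect_equal(prdn(c(0, 2), c(1, 1)), 100)
  expect_error(prdn(c(3, 3), c(1, 2)), "constant")

  expect_equal(snr(c(0, 2), c(1, 1)), 0)
  expect_identical(snr(c(0, 2), c(0, 2)), Inf)

  expect_equal(rms(1:4, 1:4), 0)
  expect_equal(rms(c(1, 0), c(0, 1)), 1)
  expect_error(rms(numeric(0), numeric(0)), "empty")

  expect_equal(qs(100, 10), 10)
  expect_equal(qs(117.33, 2.59), 45.30, tolerance = 1e-2)
  expect_equal(qs(100, 5), 2 * qs(100, 10))
  expect_error(qs(10, 0), "PRD")
})

test_that("metric invariances and the SNR/PRDN identity hold", {
  set.seed(31)
  for (i in 1:25) {
    Do <- rnorm(200); Dr <- Do + rnorm(200, sd = 0.3)
    c0 <- runif(1, -5, 5); s0 <- runif(1, 0.2, 4)
    # PRDN offset invariance, PRD scale invariance
    expect_equal(prdn(Do + c0, Dr + c0), prdn(Do, Dr), tolerance = 1e-9)
    expect_equal(prd(s0 * Do, s0 * Dr), prd(Do, Dr), tolerance = 1e-9)
    expect_equal(rms(s0 * Do, s0 * Dr), s0 * rms(Do, Dr), tolerance = 1e-9)
    # snr = 40 - 20 log10(prdn)
    expect_equal(snr(Do, Dr), 40 - 20 * log10(prdn(Do, Dr)),
                 tolerance = 1e-9)
  }
  # halving the error energy adds 10 log10(2) dB
  Do <- rnorm(300); e <- rnorm(300)
  expect_equal(snr(Do, Do + e / sqrt(2)) - snr(Do, Do + e),
               10 * log10(2), tolerance = 1e-9)
})

test_that("aggregate rows are means of per-record metrics", {
  mk <- function(prd_target) {
    Do <- sin(seq(0, 20, length.out = 500)) + 2
    err <- rnorm(500)
    err <- err / sqrt(sum(err^2)) * sqrt(sum(Do^2)) * prd_target / 100
    list(original = Do, reconstructed = Do - err, n_beats = 10L,
         bits_in = 35200, bits_out = 300)
  }
  set.seed(32)
  tab <- evaluate_compression(list(a = mk(10), b = mk(30)))
  expect_identical(nrow(tab), 3L)
  expect_equal(tab$prd[1], 10, tolerance = 1e-9)
  expect_equal(tab$prd[2], 30, tolerance = 1e-9)
  avg <- tab[tab$record == "average", ]
  expect_equal(avg$prd, 20, tolerance = 1e-9)
  expect_equal(avg$cr, 117.33, tolerance = 1e-2)
  # QS is averaged per record, which differs from CR / mean PRD
  expect_equal(avg$qs, mean(tab$qs[1:2]), tolerance = 1e-9)
  expect_gt(avg$qs, avg$cr / avg$prd)  # Jensen: mean(1/x) > 1/mean(x)
})

test_that("metrics equal independent one-line re-derivations in bulk", {
  set.seed(33)
  for (i in 1:1000) {
    L <- sample(20:60, 1)
    Do <- rnorm(L, mean = runif(1, -2, 2))
    Dr <- Do + rnorm(L, sd = runif(1, 0.05, 1))
    expect_equal(prd(Do, Dr),
                 100 * sqrt(sum((Do - Dr)^2) / sum(Do^2)), tolerance = 1e-9)
    expect_equal(prdn(Do, Dr),
                 100 * sqrt(sum((Do - Dr)^2) / sum((Do - mean(Do))^2)),
                 tolerance = 1e-9)
    expect_equal(snr(Do, Dr),
                 10 * log10(sum((Do - mean(Do))^2) / sum((Do - Dr)^2)),
                 tolerance = 1e-9)
    expect_equal(rms(Do, Dr), sqrt(sum((Do - Dr)^2) / L), tolerance = 1e-9)
  }
})
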