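test_that("pseudo-Huber loss matches its closed form", {
  x <- runif(100)
  expect_equal(pseudo_huber_loss(x, x), 0)
  # single residual of delta: delta^2 (sqrt(2) - 1)
  expect_equal(pseudo_huber_loss(0.9, 0, delta = 0.9),
               0.81 * (sqrt(2) - 1), tolerance = 1e-12)
  expect_equal(pseudo_huber_loss(0.9, 0, delta = 0.9), 0.33552,
               tolerance = 1e-4)
  # quadratic regime: loss / (r^2/2) -> 1 as r -> 0
  r <- 1e-5
  expect_equal(pseudo_huber_loss(r, 0, delta = 0.9) / (r^2 / 2), 1,
               tolerance = 1e-6)
  # non-negativity on random pairs
  set.seed(1)
  for (i in 1:20) {
    a <- rnorm(50); b <- rnorm(50)
    expect_gte(pseudo_huber_loss(a, b), 0)
  }
  expect_error(pseudo_huber_loss(1:3, 1:4), "lengths")
})

dummy_beats <- function(n_records, beats_per_record, nrow = 2L) {
  n <- n_records * beats_per_record
  structure(list(samples = matrix(rnorm(nrow * n), nrow, n),
                 r_index = seq_len(n),
                 record_id = rep(sprintf("r%02d", seq_len(n_records)),
                                 each = beats_per_record),
                 fs = 360),
            class = "becg_beats")
}

test_that("the default split of 48 x 1000 beats is 38400/7200/2400", {
  beats <- dummy_beats(48L, 1000L)
  parts <- split_dataset(beats, split_spec(), seed = 4)
  expect_identical(ncol(parts$train$samples), 38400L)
  expect_identical(ncol(parts$val$samples), 7200L)
  expect_identical(ncol(parts$test$samples), 2400L)
  # 50 test beats from every record
  expect_true(all(table(parts$test$record_id) == 50L))
})

test_that("splits partition the input and are seed-deterministic", {
  beats <- dummy_beats(4L, 40L)
  sp <- split_spec(per_record_beats = 40L, test_per_record = 4L)
  parts <- split_dataset(beats, sp, seed = 1)
  ids <- lapply(parts, function(p) sort(p$r_index))
  expect_identical(sort(unname(unlist(ids))), beats$r_index)
  expect_identical(length(intersect(ids$train, ids$test)), 0L)
  expect_identical(length(intersect(ids$train, ids$val)), 0L)
  parts2 <- split_dataset(beats, sp, seed = 1)
  expect_identical(parts, parts2)
  expect_false(identical(parts, split_dataset(beats, sp, seed = 2)))
  expect_warning(split_dataset(dummy_beats(1L, 5L),
                               split_spec(per_record_beats = 10L,
                                          test_per_record = 1L)),
                 "only")
})

test_that("one training epoch runs and reports a finite loss", {
  set.seed(2)
  x <- matrix(runif(320 * 10), 320, 10)
  cfg <- train_config(epochs = 1L, batch_size = 4L, seed = 2)
  m <- train_bcae(x, NULL, config = cfg)
  expect_identical(nrow(m$history), 1L)
  expect_true(is.finite(m$history$train_loss))
  expect_error(train_bcae(matrix(numeric(0), 320, 0), config = cfg), "empty")
})

test_that("gradients reach the encoder only through the surrogate", {
  m <- build_bcae(seed = 6)
  set.seed(6)
  x <- matrix(runif(320 * 8), 320, 8)
  g_surr <- encoder_gradient_norm(m, x, surrogate = TRUE)
  g_hard <- encoder_gradient_norm(m, x, surrogate = FALSE)
  expect_gt(g_surr, 0)
  expect_identical(g_hard, 0)
})

test_that("training a run twice with one seed is bit-reproducible", {
  set.seed(3)
  x <- matrix(runif(320 * 16), 320, 16)
  cfg <- train_config(epochs = 2L, batch_size = 8L, seed = 11)
  m1 <- train_bcae(x, x[, 1:4], config = cfg)
  m2 <- train_bcae(x, x[, 1:4], config = cfg)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$history, m2$history)
})
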