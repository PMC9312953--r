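test_that("step activation and surrogate gradient match their piecewise
           definitions at and around the boundaries", {
  expect_equal(step_activation(0), 1)
  expect_equal(step_activation(-0.3), 0)
  expect_equal(step_activation(c(-1e-12, 1e-12, 5, -5)), c(0, 1, 1, 0))
  x <- rnorm(1000)
  expect_true(all(step_activation(x) %in% c(0, 1)))

  expect_equal(step_surrogate_gradient(0), 1)
  expect_equal(step_surrogate_gradient(-0.5), 1)  # left boundary included
  expect_equal(step_surrogate_gradient(0.5), 0)   # right boundary excluded
  expect_equal(step_surrogate_gradient(0.6), 0)
  expect_equal(step_surrogate_gradient(-0.6), 0)
})

test_that("conv1d matches hand cases and the brute-force oracle", {
  # identity kernel passes the input through
  w <- array(0, c(3, 1, 1)); w[2, 1, 1] <- 1
  x <- rnorm(16)
  expect_equal(drop(conv1d(x, w)), x)

  # zero weights with tanh give zeros
  wz <- array(0, c(5, 2, 3))
  expect_equal(conv1d(matrix(rnorm(20), 10, 2), wz, activation = "tanh"),
               matrix(0, 10, 3))

  expect_error(conv1d(matrix(rnorm(20), 10, 2), array(0, c(3, 3, 1))),
               "mismatch")

  set.seed(101)
  for (i in 1:40) {
    K <- sample(1:7, 1); cin <- sample(1:3, 1); cout <- sample(1:3, 1)
    L <- sample(c(8, 9, 12), 1)
    x <- matrix(rnorm(L * cin), L, cin)
    w <- random_weights(K, cin, cout)
    b <- rnorm(cout)
    expect_equal(conv1d(x, w, b), oracle_conv(x, w, b), tolerance = 1e-10)
  }
})

test_that("tconv1d is conv1d's adjoint and matches its oracle", {
  # odd symmetric kernel: transposed convolution equals convolution
  w <- array(c(0.2, 0.5, 0.2), c(3, 1, 1))
  x <- rnorm(12)
  expect_equal(tconv1d(x, w), conv1d(x, w))

  # zero input passes the bias through the activation
  wz <- random_weights(4, 1, 2)
  out <- tconv1d(rep(0, 10), wz, b = c(0.3, -0.2), activation = "tanh")
  expect_equal(out, matrix(rep(tanh(c(0.3, -0.2)), each = 10), 10, 2))

  set.seed(202)
  for (i in 1:40) {
    K <- sample(1:7, 1); cin <- sample(1:3, 1); cout <- sample(1:3, 1)
    L <- sample(c(8, 9, 12), 1)
    x <- matrix(rnorm(L * cin), L, cin)
    w <- random_weights(K, cin, cout)
    b <- rnorm(cout)
    expect_equal(tconv1d(x, w, b), oracle_tconv(x, w, b), tolerance = 1e-10)
  }

  # adjoint identity: <conv(x), y> == <x, tconv(y)> for single-channel maps
  set.seed(203)
  for (i in 1:20) {
    K <- sample(1:8, 1); L <- 16
    w <- random_weights(K, 1, 1)
    x <- rnorm(L); y <- rnorm(L)
    expect_equal(sum(conv1d(x, w) * y), sum(x * tconv1d(y, w)),
                 tolerance = 1e-10)
  }
})

test_that("maxpool keeps window maxima and rejects ragged input", {
  expect_equal(maxpool(c(1, 3, 2, 5)), c(3, 5))
  expect_equal(maxpool(rep(2, 8)), rep(2, 4))
  x <- sort(rnorm(12))  # monotone: last element of each window
  expect_equal(maxpool(x, 3), x[c(3, 6, 9, 12)])
  expect_error(maxpool(rnorm(7), 2), "divisible")
})

test_that("zero-insertion upsampling inverts maxpool on its support", {
  expect_equal(upsample_zero(c(3, 7)), c(3, 0, 7, 0))
  expect_equal(upsample_zero(rep(0, 4), 3), rep(0, 12))
  x <- abs(rnorm(10))
  expect_equal(maxpool(upsample_zero(x, 2), 2), x)
})

test_that("linear output layer is an unconstrained affine map", {
  x <- rnorm(8)
  expect_equal(linear_out(x, diag(8)), x)
  expect_equal(linear_out(x, matrix(0, 8, 3), b = c(5, -2, 0.5)),
               c(5, -2, 0.5))
  set.seed(303)
  for (i in 1:20) {
    n_in <- sample(2:6, 1); n_out <- sample(2:6, 1)
    w <- matrix(rnorm(n_in * n_out), n_in, n_out)
    b <- rnorm(n_out)
    x <- rnorm(n_in)
    expect_equal(linear_out(x, w, b), oracle_linear(x, w, b),
                 tolerance = 1e-12)
  }
  expect_error(linear_out(rnorm(5), diag(8)), "mismatch")
})

test_that("weight layout conversion round-trips", {
  set.seed(404)
  w <- random_weights(5, 3, 4)
  expect_equal(weight_array(weight_matrix(w), 5, 3), w)
})
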