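#' Step activation of the binary encoding layer
#'
#' Elementwise hard threshold: 0 for `x < 0`, 1 for `x >= 0`. This is the
#' forward activation of the binary encoding layer (BEL), which turns the
#' bottleneck features into binary code bits.
#'
#' @param x Numeric vector/matrix of pre-activations.
#' @return Binary values of the same shape.
#' @export
step_activation <- function(x) {
  out <- x
  out[] <- as.numeric(x >= 0)
  out
}

#' Surrogate gradient of the step activation
#'
#' The step function has zero derivative almost everywhere, so the backward
#' pass uses a straight-through surrogate: 1 on \[-0.5, 0.5) and 0
#' elsewhere. Downstream gradients through the binary encoding layer are
#' multiplied by this mask.
#'
#' @param x Numeric vector/matrix of pre-activations.
#' @return Gradient mask of the same shape.
#' @export
step_surrogate_gradient <- function(x) {
  out <- x
  out[] <- as.numeric(x >= -0.5 & x < 0.5)
  out
}

pad_left <- function(K) (K - 1L) %/% 2L

apply_act <- function(y, activation) {
  switch(activation,
         none = y,
         tanh = tanh(y),
         relu = pmax(y, 0),
         step = step_activation(y),
         stop("unknown activation: ", activation))
}

#' 1-D convolution (stride 1, "same" padding)
#'
#' Sliding-window correlation of the input channels with the kernel bank,
#' plus bias, through the given activation. Output length equals input
#' length; zero padding totals `kernel - 1` samples with the left side
#' getting the floor.
#'
#' @param x Input: numeric vector (one channel) or `L x Cin` matrix.
#' @param w Weight array of dimension `(K, Cin, Cout)`.
#' @param b Bias vector of length `Cout` (default zeros).
#' @param activation One of `"none"`, `"tanh"`, `"relu"`.
#' @return `L x Cout` matrix of feature maps.
#' @export
conv1d <- function(x, w, b = NULL, activation = "none") {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1L)
  stopifnot(length(dim(w)) == 3L)
  K <- dim(w)[1]; cin <- dim(w)[2]; cout <- dim(w)[3]
  if (ncol(x) != cin)
    stop("shape mismatch: input has ", ncol(x), " channels, kernel expects ",
         cin)
  if (is.null(b)) b <- numeric(cout)
  L <- nrow(x)
  padL <- pad_left(K)
  xp <- rbind(matrix(0, padL, cin), x, matrix(0, K - 1L - padL, cin))
  y <- matrix(0, L, cout)
  for (k in seq_len(K)) {
    wk <- matrix(w[k, , ], nrow = cin, ncol = cout)
    y <- y + xp[k:(k + L - 1L), , drop = FALSE] %*% wk
  }
  y <- sweep(y, 2L, b, `+`)
  apply_act(y, activation)
}

#' 1-D transposed convolution (stride 1, "same" padding)
#'
#' The exact adjoint of [conv1d()]: kernel taps are flipped and the zero
#' padding is mirrored, so for a symmetric odd-length kernel the two
#' operators coincide.
#'
#' @inheritParams conv1d
#' @return `L x Cout` matrix of feature maps.
#' @export
tconv1d <- function(x, w, b = NULL, activation = "none") {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1L)
  stopifnot(length(dim(w)) == 3L)
  K <- dim(w)[1]
  wf <- w[K:1, , , drop = FALSE]                       # flip taps
  dim(wf) <- dim(w)
  # mirrored padding: emulate by padding the flipped-kernel correlation
  cin <- dim(w)[2]; cout <- dim(w)[3]
  if (ncol(x) != cin)
    stop("shape mismatch: input has ", ncol(x), " channels, kernel expects ",
         cin)
  if (is.null(b)) b <- numeric(cout)
  L <- nrow(x)
  padL <- K - 1L - pad_left(K)
  xp <- rbind(matrix(0, padL, cin), x, matrix(0, K - 1L - padL, cin))
  y <- matrix(0, L, cout)
  for (k in seq_len(K)) {
    wk <- matrix(wf[k, , ], nrow = cin, ncol = cout)
    y <- y + xp[k:(k + L - 1L), , drop = FALSE] %*% wk
  }
  y <- sweep(y, 2L, b, `+`)
  apply_act(y, activation)
}

#' Non-overlapping max pooling
#'
#' @param x Input: numeric vector or `L x C` matrix; `L` must be divisible
#'   by `size`.
#' @param size Pooling window (= stride).
#' @return `(L/size) x C` matrix (or vector for single-channel vector
#'   input).
#' @export
maxpool <- function(x, size = 2L) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, ncol = 1L)
  L <- nrow(x)
  if (L %% size != 0L)
    stop("input length ", L, " not divisible by pooling size ", size)
  out <- apply(x, 2L, function(col)
    vapply(seq_len(L %/% size),
           function(n) max(col[((n - 1L) * size + 1L):(n * size)]),
           numeric(1)))
  out <- matrix(out, ncol = ncol(x))
  if (vec) drop(out) else out
}

#' Zero-insertion up-sampling
#'
#' Each input value is placed in the first slot of its output window; the
#' remaining `size - 1` slots are zero.
#'
#' @param x Input: numeric vector or `L x C` matrix.
#' @param size Up-sampling factor.
#' @return `(L*size) x C` matrix (or vector for vector input).
#' @export
upsample_zero <- function(x, size = 2L) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, ncol = 1L)
  out <- matrix(0, nrow(x) * size, ncol(x))
  out[seq(1L, nrow(out), by = size), ] <- x
  if (vec) drop(out) else out
}

#' Linear output layer
#'
#' Affine map with no activation; unlike the tanh-limited transposed
#' convolutions its output is not confined to \[-1, 1\], which lets it
#' restore the reconstructed beat's amplitude.
#'
#' @param x Input vector (or `L x 1` matrix), flattened.
#' @param w Weight matrix `(n_in x n_out)`.
#' @param b Bias vector of length `n_out` (default zeros).
#' @return Numeric vector of length `n_out`.
#' @export
linear_out <- function(x, w, b = NULL) {
  x <- as.numeric(x)
  if (length(x) != nrow(w))
    stop("shape mismatch: input length ", length(x), ", weights expect ",
         nrow(w))
  if (is.null(b)) b <- numeric(ncol(w))
  drop(crossprod(w, x)) + b
}
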