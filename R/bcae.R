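layer_spec <- function(kind, size = 1L, cin = 1L, cout = 1L, len_in = 0L,
                       len_out = 0L, activation = "none", bn = FALSE,
                       dropout = FALSE) {
  list(kind = kind, size = as.integer(size), cin = as.integer(cin),
       cout = as.integer(cout), len_in = as.integer(len_in),
       len_out = as.integer(len_out), activation = activation, bn = bn,
       dropout = dropout)
}

#' Default BCAE layer specification
#'
#' The 28-layer stack of the binary convolutional autoencoder: a
#' 9-convolution encoder with 4 max-pooling stages and the binary encoding
#' layer (BEL), then a 9-transposed-convolution decoder with 4 zero-insertion
#' up-sampling stages and a final linear layer. The encoder maps a
#' 320-sample beat to a 20-bit binary code; the decoder maps the code back
#' to 320 samples. Batch normalization follows every convolution except the
#' first encoder convolution and the first decoder transposed convolution;
#' dropout is applied at two decoder sites only.
#'
#' @return A list of layer descriptors (one per layer, in execution order).
#' @export
bcae_spec <- function() {
  list(
    layer_spec("conv",     8,  1,  4, 320, 320, "tanh", bn = FALSE),
    layer_spec("conv",    32,  4,  8, 320, 320, "tanh", bn = TRUE),
    layer_spec("maxpool",  2,  8,  8, 320, 160),
    layer_spec("conv",    64,  8, 16, 160, 160, "tanh", bn = TRUE),
    layer_spec("conv",    96, 16, 32, 160, 160, "tanh", bn = TRUE),
    layer_spec("maxpool",  2, 32, 32, 160,  80),
    layer_spec("conv",    64, 32, 64,  80,  80, "tanh", bn = TRUE),
    layer_spec("conv",    32, 64, 64,  80,  80, "tanh", bn = TRUE),
    layer_spec("maxpool",  2, 64, 64,  80,  40),
    layer_spec("conv",    16, 64, 32,  40,  40, "tanh", bn = TRUE),
    layer_spec("conv",     8, 32, 16,  40,  40, "tanh", bn = TRUE),
    layer_spec("maxpool",  2, 16, 16,  40,  20),
    layer_spec("conv",     8, 16,  1,  20,  20, "tanh", bn = TRUE),
    layer_spec("bel",      1,  1,  1,  20,  20, "step"),
    layer_spec("tconv",    8,  1,  1,  20,  20, "tanh", bn = FALSE),
    layer_spec("upsample", 2,  1,  1,  20,  40),
    layer_spec("tconv",    8,  1, 16,  40,  40, "tanh", bn = TRUE, dropout = TRUE),
    layer_spec("tconv",   16, 16, 32,  40,  40, "tanh", bn = TRUE),
    layer_spec("upsample", 2, 32, 32,  40,  80),
    layer_spec("tconv",   32, 32, 64,  80,  80, "tanh", bn = TRUE),
    layer_spec("tconv",   64, 64, 64,  80,  80, "tanh", bn = TRUE),
    layer_spec("upsample", 2, 64, 64,  80, 160),
    layer_spec("tconv",   96, 64, 32, 160, 160, "tanh", bn = TRUE, dropout = TRUE),
    layer_spec("tconv",   64, 32, 16, 160, 160, "tanh", bn = TRUE),
    layer_spec("upsample", 2, 16, 16, 160, 320),
    layer_spec("tconv",   32, 16,  8, 320, 320, "tanh", bn = TRUE),
    layer_spec("tconv",    8,  8,  1, 320, 320, "tanh", bn = TRUE),
    layer_spec("linear",   0,  1,  1, 320, 320, "none"))
}

#' Symbolically trace the output sizes of a layer stack
#'
#' @param spec List of layer descriptors (see [bcae_spec()]).
#' @param len_in,cin Input length and channel count.
#' @return A data.frame with one row per layer: `layer`, `kind`, `len`,
#'   `channels` (the layer's output size).
#' @export
trace_spec <- function(spec, len_in = 320L, cin = 1L) {
  len <- len_in; ch <- cin
  out <- data.frame(layer = integer(0), kind = character(0),
                    len = integer(0), channels = integer(0))
  for (i in seq_along(spec)) {
    l <- spec[[i]]
    if (l$cin != ch)
      stop("layer ", i, " (", l$kind, "): expects ", l$cin,
           " input channels but receives ", ch)
    if (l$len_in != len)
      stop("layer ", i, " (", l$kind, "): expects input length ", l$len_in,
           " but receives ", len)
    len <- switch(l$kind,
      conv = , tconv = , bel = len,
      maxpool = {
        if (len %% l$size != 0L)
          stop("layer ", i, ": length ", len, " not divisible by pool size")
        len %/% l$size
      },
      upsample = len * l$size,
      linear = l$len_out,
      stop("layer ", i, ": unknown kind ", l$kind))
    ch <- switch(l$kind, conv = , tconv = l$cout, l$cout)
    if (l$len_out != len)
      stop("layer ", i, " (", l$kind, "): declared output length ", l$len_out,
           " does not match traced length ", len)
    out <- rbind(out, data.frame(layer = i, kind = l$kind, len = len,
                                 channels = ch))
  }
  out
}

#' Convert between convolution weight layouts
#'
#' Model parameters store each convolution's weights as a
#' `(K*Cin) x Cout` matrix whose row index runs over the input channel
#' fastest; the layer operators ([conv1d()], [tconv1d()]) take a
#' `(K, Cin, Cout)` array. These helpers convert between the two layouts.
#'
#' @param w A `(K, Cin, Cout)` weight array.
#' @return `weight_matrix()`: the `(K*Cin) x Cout` matrix.
#' @export
weight_matrix <- function(w) {
  stopifnot(length(dim(w)) == 3L)
  d <- dim(w)
  matrix(aperm(w, c(2L, 1L, 3L)), d[1] * d[2], d[3])
}

#' @rdname weight_matrix
#' @param W A `(K*Cin) x Cout` weight matrix.
#' @param K,cin Kernel size and input channel count.
#' @return `weight_array()`: the `(K, Cin, Cout)` array.
#' @export
weight_array <- function(W, K, cin) {
  cout <- ncol(W)
  aperm(array(W, dim = c(cin, K, cout)), c(2L, 1L, 3L))
}

glorot <- function(fan_in, fan_out, n) {
  a <- sqrt(6 / (fan_in + fan_out))
  stats::runif(n, -a, a)
}

init_layer_params <- function(l) {
  if (l$kind %in% c("maxpool", "upsample", "bel")) return(NULL)
  if (l$kind == "linear") {
    n_in <- l$len_in * l$cin; n_out <- l$len_out
    return(list(W = matrix(glorot(n_in, n_out, n_in * n_out), n_in, n_out),
                b = numeric(n_out)))
  }
  K <- l$size
  p <- list(W = matrix(glorot(K * l$cin, K * l$cout, K * l$cin * l$cout),
                       K * l$cin, l$cout),
            b = numeric(l$cout))
  if (l$bn) {
    p$gamma <- rep(1, l$cout); p$beta <- numeric(l$cout)
    p$rmean <- numeric(l$cout); p$rvar <- rep(1, l$cout)
  }
  p
}

#' Build a BCAE model
#'
#' Validates the layer stack against the canonical output-size trace (any
#' mismatch is an error naming the offending layer) and initializes weights
#' with Glorot-uniform draws under the given seed. Batch-norm scale/shift
#' start at 1/0 with unit running variance.
#'
#' @param spec Layer specification, default [bcae_spec()].
#' @param seed Integer seed for weight initialization.
#' @return An object of class `becg_bcae` with elements `spec`, `params`,
#'   `code_layer` (index of the BEL), `code_bits`.
#' @export
build_bcae <- function(spec = bcae_spec(), seed = 1L) {
  tr <- trace_spec(spec, len_in = spec[[1]]$len_in, cin = spec[[1]]$cin)
  code_layer <- which(vapply(spec, `[[`, character(1), "kind") == "bel")
  if (length(code_layer) != 1L)
    stop("spec must contain exactly one binary encoding layer")
  code_bits <- tr$len[code_layer] * tr$channels[code_layer]
  params <- with_seed(seed, lapply(spec, init_layer_params))
  structure(list(spec = spec, params = params, trace = tr,
                 code_layer = code_layer, code_bits = code_bits,
                 history = NULL),
            class = "becg_bcae")
}

#' @export
print.becg_bcae <- function(x, ...) {
  cat(sprintf("<becg_bcae: %d layers, %d-bit binary code, input %d samples%s>\n",
              length(x$spec), x$code_bits, x$spec[[1]]$len_in,
              if (is.null(x$history)) " (untrained)" else " (trained)"))
  invisible(x)
}

as_beat_matrix <- function(beats, nrow_expect = 320L) {
  x <- if (inherits(beats, "becg_beats")) beats$samples else beats
  if (is.null(dim(x))) x <- matrix(x, ncol = 1L)
  if (nrow(x) != nrow_expect)
    stop("expected ", nrow_expect, "-sample input, got ", nrow(x))
  x
}

#' Encode beats to binary codes
#'
#' Runs the encoder stack (through the binary encoding layer) in inference
#' mode. Each 320-sample beat becomes a 20-bit binary column.
#'
#' @param model A trained or untrained [build_bcae()] model.
#' @param beats `becg_beats` container or numeric `320 x n` matrix.
#' @return Integer `code_bits x n` matrix with entries in \{0, 1\}.
#' @export
bcae_encode <- function(model, beats) {
  stopifnot(inherits(model, "becg_bcae"))
  x <- as_beat_matrix(beats, model$spec[[1]]$len_in)
  enc <- seq_len(model$code_layer)
  out <- cpp_bcae_run(model$spec[enc], model$params[enc], x)
  storage.mode(out) <- "integer"
  out
}

#' Decode binary codes to reconstructed beats
#'
#' Runs the decoder stack in inference mode. Dropout is inactive and batch
#' normalization uses running statistics, so decoding is deterministic.
#'
#' @param model A [build_bcae()] model.
#' @param codes Integer/numeric `code_bits x n` matrix of 0/1 code columns.
#' @return Numeric `320 x n` matrix of reconstructed beats.
#' @export
bcae_decode <- function(model, codes) {
  stopifnot(inherits(model, "becg_bcae"))
  if (is.null(dim(codes))) codes <- matrix(codes, ncol = 1L)
  if (nrow(codes) != model$code_bits)
    stop("expected ", model$code_bits, "-bit codes, got ", nrow(codes), " rows")
  if (!all(codes %in% c(0, 1))) stop("codes must be binary (0/1)")
  dec <- (model$code_layer + 1L):length(model$spec)
  cpp_bcae_run(model$spec[dec], model$params[dec], codes)
}

#' Full autoencoder pass (encode then decode)
#'
#' @param model A [build_bcae()] model.
#' @param beats `becg_beats` container or `320 x n` matrix.
#' @return List with `code` (bits) and `output` (reconstruction).
#' @export
bcae_forward <- function(model, beats) {
  stopifnot(inherits(model, "becg_bcae"))
  x <- as_beat_matrix(beats, model$spec[[1]]$len_in)
  res <- cpp_bcae_forward(model$spec, model$params, x, model$code_layer)
  res$code <- round(res$code)
  storage.mode(res$code) <- "integer"
  res
}
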