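# Independent brute-force oracles for the layer operators: plain sliding
# dot products written directly from the operator definitions, kept free of
# any package internals.

oracle_conv <- function(x, w, b = NULL) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1L)
  K <- dim(w)[1]; cin <- dim(w)[2]; cout <- dim(w)[3]
  if (is.null(b)) b <- numeric(cout)
  L <- nrow(x)
  padL <- (K - 1L) %/% 2L
  y <- matrix(0, L, cout)
  for (t in seq_len(L))
    for (o in seq_len(cout)) {
      acc <- b[o]
      for (k in seq_len(K))
        for (c in seq_len(cin)) {
          s <- t - padL + (k - 1L)
          if (s >= 1L && s <= L) acc <- acc + x[s, c] * w[k, c, o]
        }
      y[t, o] <- acc
    }
  y
}

oracle_tconv <- function(x, w, b = NULL) {
  # adjoint of oracle_conv: flipped taps, mirrored padding
  K <- dim(w)[1]
  wf <- w[K:1, , , drop = FALSE]
  dim(wf) <- dim(w)
  if (is.null(dim(x))) x <- matrix(x, ncol = 1L)
  cin <- dim(w)[2]; cout <- dim(w)[3]
  if (is.null(b)) b <- numeric(cout)
  L <- nrow(x)
  padL <- K - 1L - (K - 1L) %/% 2L
  y <- matrix(0, L, cout)
  for (t in seq_len(L))
    for (o in seq_len(cout)) {
      acc <- b[o]
      for (k in seq_len(K))
        for (c in seq_len(cin)) {
          s <- t - padL + (k - 1L)
          if (s >= 1L && s <= L) acc <- acc + x[s, c] * wf[k, c, o]
        }
      y[t, o] <- acc
    }
  y
}

oracle_linear <- function(x, w, b = NULL) {
  x <- as.numeric(x)
  if (is.null(b)) b <- numeric(ncol(w))
  out <- numeric(ncol(w))
  for (o in seq_len(ncol(w))) out[o] <- sum(x * w[, o]) + b[o]
  out
}

random_weights <- function(K, cin, cout) {
  array(stats::rnorm(K * cin * cout), dim = c(K, cin, cout))
}

# Run the model's layer stack with the R reference operators (independent of
# the C++ forward pass) in inference mode.
r_reference_stack <- function(model, x, layers) {
  a <- matrix(x, ncol = 1L)
  for (i in layers) {
    l <- model$spec[[i]]
    p <- model$params[[i]]
    if (l$kind %in% c("conv", "tconv")) {
      w <- weight_array(p$W, l$size, l$cin)
      f <- if (l$kind == "conv") conv1d else tconv1d
      a <- f(a, w, p$b, activation = "none")
      if (l$bn)
        a <- sweep(sweep(sweep(sweep(a, 2, p$rmean, "-"),
                               2, sqrt(p$rvar + 1e-5), "/"),
                         2, p$gamma, "*"), 2, p$beta, "+")
      if (l$activation == "tanh") a <- tanh(a)
    } else if (l$kind == "maxpool") a <- maxpool(a, l$size)
    else if (l$kind == "upsample") a <- upsample_zero(a, l$size)
    else if (l$kind == "bel") a <- step_activation(a)
    else if (l$kind == "linear") a <- matrix(linear_out(a, p$W, p$b), ncol = 1L)
  }
  a
}

clean_rhythm <- function(n_beats = 10L, ...)
  rhythm_params(n_beats = n_beats, noise_sd = 0, baseline_amp = 0, ...)
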