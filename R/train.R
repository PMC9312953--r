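#' Pseudo-Huber loss
#'
#' Smooth approximation to the Huber loss, quadratic for small residuals
#' and linear in the tails, averaged over samples:
#' `mean(delta^2 * (sqrt(1 + ((y - y')/delta)^2) - 1))`. The shape
#' parameter `delta` (0.9) controls where the quadratic regime hands over
#' to the linear one, damping the influence of noisy extremes.
#'
#' @param y Original signal (vector or matrix).
#' @param y_prime Reconstruction, same shape.
#' @param delta Shape parameter (> 0).
#' @return Scalar loss (>= 0; 0 iff `y == y_prime`).
#' @export
pseudo_huber_loss <- function(y, y_prime, delta = 0.9) {
  if (length(y) != length(y_prime)) stop("signals have different lengths")
  stopifnot(delta > 0)
  r <- (as.numeric(y) - as.numeric(y_prime)) / delta
  mean(delta^2 * (sqrt(1 + r^2) - 1))
}

#' Training configuration
#'
#' Defaults follow the reference training protocol: pseudo-Huber shape 0.9,
#' Adagrad with initial learning rate 0.1, batch size 256, 400 epochs.
#'
#' @param delta Pseudo-Huber shape parameter.
#' @param learning_rate Initial Adagrad learning rate.
#' @param batch_size Mini-batch size.
#' @param epochs Number of passes over the training set.
#' @param seed Integer seed (shuffling, dropout).
#' @param optimizer Optimizer name; only `"adagrad"` is available.
#' @param dropout_rate Dropout probability at the two decoder dropout sites.
#' @param keep_best Keep the parameters of the best-validation epoch rather
#'   than the last.
#' @return A list of class `becg_train_config`.
#' @export
train_config <- function(delta = 0.9, learning_rate = 0.1, batch_size = 256L,
                         epochs = 400L, seed = 1L, optimizer = "adagrad",
                         dropout_rate = 0.25, keep_best = TRUE) {
  stopifnot(delta > 0, batch_size >= 1L, epochs >= 1L)
  optimizer <- match.arg(optimizer, "adagrad")
  structure(list(delta = delta, learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 optimizer = optimizer, dropout_rate = dropout_rate,
                 keep_best = keep_best),
            class = "becg_train_config")
}

#' Dataset split specification
#'
#' Defaults reproduce the reference protocol: 1000 beats per record,
#' 80/15/5 train/validation/test split with the test set holding 50 beats
#' from each record.
#'
#' @param train_frac,val_frac,test_frac Split fractions (must sum to 1).
#' @param per_record_beats Beats sampled per record.
#' @param test_per_record Test beats per record.
#' @return A list of class `becg_split_spec`.
#' @export
split_spec <- function(train_frac = 0.80, val_frac = 0.15, test_frac = 0.05,
                       per_record_beats = 1000L, test_per_record = 50L) {
  if (abs(train_frac + val_frac + test_frac - 1) > 1e-9)
    stop("split fractions must sum to 1")
  structure(list(train_frac = train_frac, val_frac = val_frac,
                 test_frac = test_frac,
                 per_record_beats = as.integer(per_record_beats),
                 test_per_record = as.integer(test_per_record)),
            class = "becg_split_spec")
}

#' Split a beat corpus into train/validation/test sets
#'
#' Stratified by record: from each record `per_record_beats` beats are
#' sampled (all beats, with a warning, if a record has fewer), the test set
#' receives `test_per_record` beats per record, and the rest is divided
#' between training and validation in proportion to their fractions. The
#' partitions are disjoint and deterministic given the seed.
#'
#' @param beats A `becg_beats` container.
#' @param spec A [split_spec()].
#' @param seed Integer seed.
#' @return List with `becg_beats` elements `train`, `val`, `test`.
#' @export
split_dataset <- function(beats, spec = split_spec(), seed = 1L) {
  stopifnot(inherits(beats, "becg_beats"))
  records <- unique(beats$record_id)
  if (any(table(beats$record_id) == 0L) || length(records) == 0L)
    stop("empty record in beat corpus")
  with_seed(seed, {
    tr <- va <- te <- integer(0)
    for (rec in records) {
      idx <- which(beats$record_id == rec)
      if (length(idx) == 0L) stop("record ", rec, " has no beats")
      if (length(idx) < spec$per_record_beats)
        warning("record ", rec, " has only ", length(idx), " beats (wanted ",
                spec$per_record_beats, "); using all", call. = FALSE)
      n <- min(length(idx), spec$per_record_beats)
      idx <- sample(idx, n)
      n_te <- min(spec$test_per_record, n)
      rest <- n - n_te
      n_tr <- round(rest * spec$train_frac / (spec$train_frac + spec$val_frac))
      te <- c(te, idx[seq_len(n_te)])
      tr <- c(tr, idx[n_te + seq_len(n_tr)])
      va <- c(va, idx[setdiff(seq_len(n), seq_len(n_te + n_tr))])
    }
    list(train = subset_beats(beats, tr), val = subset_beats(beats, va),
         test = subset_beats(beats, te))
  })
}

#' Train the BCAE
#'
#' Minimizes the pseudo-Huber reconstruction loss of `decode(encode(y))` by
#' backpropagation with Adagrad; the gradient passes through the binary
#' encoding layer via the straight-through surrogate
#' ([step_surrogate_gradient()]). Batch-norm statistics are updated during
#' training and frozen for inference.
#'
#' @param train,val `becg_beats` containers (or `320 x n` matrices); `val`
#'   may be `NULL`.
#' @param model A [build_bcae()] model (weights are the starting point).
#' @param config A [train_config()].
#' @return The model with trained parameters and a `history` data.frame
#'   (`epoch`, `train_loss`, `val_loss`).
#' @export
train_bcae <- function(train, val = NULL, model = NULL,
                       config = train_config()) {
  if (is.null(model)) model <- build_bcae(seed = config$seed)
  stopifnot(inherits(model, "becg_bcae"))
  x <- as_beat_matrix(train, model$spec[[1]]$len_in)
  if (ncol(x) == 0L) stop("empty training set")
  xv <- if (is.null(val)) matrix(numeric(0), nrow(x), 0L)
        else as_beat_matrix(val, model$spec[[1]]$len_in)
  res <- cpp_bcae_train(model$spec, model$params, x, xv, unclass(config))
  model$params <- res$params
  model$history <- data.frame(epoch = seq_along(res$train_loss),
                              train_loss = res$train_loss,
                              val_loss = res$val_loss)
  model
}

#' Train the RECN against a frozen BCAE
#'
#' Two-stage protocol: after BCAE training, each training beat is encoded
#' and decoded by the frozen BCAE; the RECN is fit to the x10-magnified
#' residual labels ([residual_label()]) from the 20-bit codes, with the same
#' pseudo-Huber loss and Adagrad optimizer.
#'
#' @param train,val `becg_beats` containers (or matrices); `val` may be
#'   `NULL`.
#' @param bcae A trained [build_bcae()] model.
#' @param model A [build_recn()] model (default: fresh with `config$seed`).
#' @param config A [train_config()].
#' @return The RECN model with trained parameters and a `history`
#'   data.frame.
#' @export
train_recn <- function(train, val = NULL, bcae, model = NULL,
                       config = train_config()) {
  stopifnot(inherits(bcae, "becg_bcae"))
  if (is.null(model)) model <- build_recn(seed = config$seed)
  x <- as_beat_matrix(train, 320L)
  if (ncol(x) == 0L) stop("empty training set")
  fw <- bcae_forward(bcae, x)
  labels <- residual_label(x, fw$output, model$scale)
  if (!is.null(val)) {
    xv <- as_beat_matrix(val, 320L)
    fwv <- bcae_forward(bcae, xv)
    cv <- fwv$code; lv <- residual_label(xv, fwv$output, model$scale)
  } else {
    cv <- matrix(numeric(0), bcae$code_bits, 0L)
    lv <- matrix(numeric(0), 320L, 0L)
  }
  res <- cpp_recn_train(model$params, fw$code, labels, cv, lv,
                        unclass(config))
  model$params <- res$params
  model$history <- data.frame(epoch = seq_along(res$train_loss),
                              train_loss = res$train_loss,
                              val_loss = res$val_loss)
  model
}

#' Gradient flow through the binary encoding layer
#'
#' Returns the summed absolute weight gradient over all encoder
#' convolutions for one batch, with the straight-through surrogate enabled
#' or disabled. With a hard (zero-gradient) step activation no gradient
#' reaches the encoder; the surrogate is what makes the encoder trainable.
#'
#' @param model A [build_bcae()] model.
#' @param beats `becg_beats` or `320 x n` matrix.
#' @param surrogate Use the surrogate gradient (`TRUE`) or the hard step
#'   derivative (`FALSE`).
#' @return Scalar: sum of absolute encoder weight gradients.
#' @export
encoder_gradient_norm <- function(model, beats, surrogate = TRUE) {
  stopifnot(inherits(model, "becg_bcae"))
  x <- as_beat_matrix(beats, model$spec[[1]]$len_in)
  cpp_encoder_grad_norm(model$spec, model$params, x, surrogate)
}

#' Save a BCAE/RECN checkpoint
#'
#' The checkpoint is a single self-describing file: the layer specification
#' is stored next to the weights (plus optional normalization parameters),
#' so a checkpoint can be reloaded without the code that produced it.
#'
#' @param path Output file path.
#' @param bcae A [build_bcae()] model.
#' @param recn Optional [build_recn()] model.
#' @param norm_params Optional normalization parameters.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(path, bcae, recn = NULL, norm_params = NULL) {
  stopifnot(inherits(bcae, "becg_bcae"))
  obj <- list(format = "becg-checkpoint", version = 1L,
              spec_json = jsonlite::toJSON(bcae$spec, auto_unbox = TRUE),
              bcae = bcae, recn = recn, norm_params = norm_params)
  saveRDS(obj, path)
  invisible(path)
}

#' Load a checkpoint written by [save_checkpoint()]
#'
#' @param path Checkpoint file path.
#' @return List with elements `bcae`, `recn`, `norm_params`.
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "becg-checkpoint"))
    stop("not a becg checkpoint: ", path)
  obj[c("bcae", "recn", "norm_params")]
}
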