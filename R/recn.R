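#' Build the residual error compensation network (RECN)
#'
#' An MLP mapping the 20-bit binary code to a 320-sample residual
#' prediction: five ReLU hidden layers of widths 80, 140, 200, 260, 320 and
#' a final linear layer of width 320. Layers carry biases only (no batch
#' norm, no dropout). The network is trained to predict ten times the BCAE
#' reconstruction residual; see [residual_label()] and [compensate()].
#'
#' @param hidden Integer vector of hidden-layer widths.
#' @param input_width Code width (20).
#' @param output_width Residual width (must be 320).
#' @param seed Integer seed for Glorot-uniform initialization.
#' @return An object of class `becg_recn`.
#' @export
build_recn <- function(hidden = c(80L, 140L, 200L, 260L, 320L),
                       input_width = 20L, output_width = 320L, seed = 1L) {
  if (output_width != 320L)
    stop("RECN output width must be 320 (one residual sample per beat sample)")
  if (any(hidden < 1L)) stop("hidden widths must be positive")
  widths <- c(input_width, hidden, output_width)
  params <- with_seed(seed, lapply(seq_len(length(widths) - 1L), function(i) {
    n_in <- widths[i]; n_out <- widths[i + 1L]
    list(W = matrix(glorot(n_in, n_out, n_in * n_out), n_in, n_out),
         b = numeric(n_out))
  }))
  structure(list(widths = widths, params = params, scale = 10,
                 history = NULL),
            class = "becg_recn")
}

#' @export
print.becg_recn <- function(x, ...) {
  cat(sprintf("<becg_recn: %s%s>\n", paste(x$widths, collapse = " -> "),
              if (is.null(x$history)) " (untrained)" else " (trained)"))
  invisible(x)
}

#' Predict magnified residuals from binary codes
#'
#' @param model A [build_recn()] model.
#' @param codes `20 x n` matrix of binary codes.
#' @return `320 x n` matrix of predicted (x10-magnified) residuals.
#' @export
recn_predict <- function(model, codes) {
  stopifnot(inherits(model, "becg_recn"))
  if (is.null(dim(codes))) codes <- matrix(codes, ncol = 1L)
  if (nrow(codes) != model$widths[1])
    stop("expected ", model$widths[1], "-bit codes, got ", nrow(codes))
  cpp_recn_forward(model$params, codes)
}

#' Magnified residual training label
#'
#' The RECN training target is the difference between the original beat and
#' the BCAE reconstruction, magnified by `scale` (10): the residual itself
#' is small, and magnification keeps weight updates effective.
#'
#' @param original Original beats (`320 x n` matrix or vector).
#' @param bcae_output BCAE reconstructions, same shape.
#' @param scale Magnification factor (10).
#' @return `scale * (original - bcae_output)`, same shape.
#' @export
residual_label <- function(original, bcae_output, scale = 10) {
  if (length(original) != length(bcae_output))
    stop("original and reconstruction have different lengths")
  scale * (original - bcae_output)
}

#' Refine a BCAE reconstruction with the RECN residual
#'
#' The RECN output is divided by the magnification factor before it is added
#' back, inverting [residual_label()]: a perfect residual prediction
#' restores the original exactly.
#'
#' @param bcae_output BCAE reconstructions (`320 x n` matrix or vector).
#' @param recn_output RECN predictions, same shape.
#' @param scale Magnification factor (10).
#' @return Refined reconstruction, same shape.
#' @export
compensate <- function(bcae_output, recn_output, scale = 10) {
  if (length(bcae_output) != length(recn_output))
    stop("reconstruction and residual have different lengths")
  bcae_output + recn_output / scale
}
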