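#' Compression ratio
#'
#' Input bits over compressed bits. For this codec a beat of 320 11-bit
#' samples becomes one 30-bit pack, so CR = 320*11/30 = 117.33 regardless
#' of signal content.
#'
#' @param ci Input size in bits.
#' @param co Compressed size in bits (> 0).
#' @return `ci / co`.
#' @export
compression_ratio <- function(ci, co) {
  if (any(co <= 0)) stop("compressed size must be positive")
  ci / co
}

#' Percentage root-mean-square difference (PRD)
#'
#' `100 * sqrt(sum((Do - Dr)^2) / sum(Do^2))`; scale-invariant but not
#' offset-invariant (a large DC offset in `Do` deflates it).
#'
#' @param Do Original signal.
#' @param Dr Reconstructed signal, same length.
#' @return PRD in percent (>= 0).
#' @export
prd <- function(Do, Dr) {
  if (length(Do) != length(Dr)) stop("signals have different lengths")
  den <- sum(Do^2)
  if (den == 0) stop("PRD undefined for an all-zero original signal")
  100 * sqrt(sum((Do - Dr)^2) / den)
}

#' Normalized PRD (PRDN)
#'
#' PRD with the original's mean removed from the denominator:
#' `100 * sqrt(sum((Do - Dr)^2) / sum((Do - mean(Do))^2))`. Offset-invariant
#' under a common shift of both signals.
#'
#' @inheritParams prd
#' @return PRDN in percent.
#' @export
prdn <- function(Do, Dr) {
  if (length(Do) != length(Dr)) stop("signals have different lengths")
  dm <- mean(Do)
  den <- sum((Do - dm)^2)
  if (den == 0) stop("PRDN undefined for a constant original signal")
  100 * sqrt(sum((Do - Dr)^2) / den)
}

#' Signal-to-noise ratio of a reconstruction (dB)
#'
#' `10 * log10(sum((Do - mean(Do))^2) / sum((Do - Dr)^2))`. A perfect
#' reconstruction has no error energy; `Inf` is returned as the documented
#' sentinel in that case. Per signal, `snr = 40 - 20*log10(prdn)`.
#'
#' @inheritParams prd
#' @return SNR in dB (possibly `Inf`).
#' @export
snr <- function(Do, Dr) {
  if (length(Do) != length(Dr)) stop("signals have different lengths")
  dm <- mean(Do)
  sig <- sum((Do - dm)^2)
  if (sig == 0) stop("SNR undefined for a constant original signal")
  err <- sum((Do - Dr)^2)
  if (err == 0) return(Inf)
  10 * log10(sig / err)
}

#' Root-mean-square reconstruction error
#'
#' `sqrt(sum((Do - Dr)^2) / L)` with `L` the signal length.
#'
#' @inheritParams prd
#' @return RMS error in the signal's units.
#' @export
rms <- function(Do, Dr) {
  if (length(Do) == 0) stop("empty signals")
  if (length(Do) != length(Dr)) stop("signals have different lengths")
  sqrt(sum((Do - Dr)^2) / length(Do))
}

#' Quality score
#'
#' Compression ratio divided by PRD: the joint efficiency-fidelity figure
#' of merit.
#'
#' @param cr Compression ratio.
#' @param prd PRD in percent (> 0).
#' @return `cr / prd`.
#' @export
qs <- function(cr, prd) {
  if (any(prd <= 0)) stop("QS undefined for PRD <= 0")
  cr / prd
}

#' Mean per-beat PRD between two beat matrices
#'
#' @param Do,Dr `320 x n` matrices (original and reconstructed beats).
#' @return Mean of the columnwise PRD values.
#' @export
mean_beat_prd <- function(Do, Dr) {
  stopifnot(identical(dim(Do), dim(Dr)))
  mean(vapply(seq_len(ncol(Do)), function(j) prd(Do[, j], Dr[, j]),
              numeric(1)))
}

#' Compress and reconstruct one record for evaluation
#'
#' Runs the full pipeline on a raw record and returns the aligned pair of
#' preprocessed original and reconstruction. The stitched reconstruction
#' covers exactly the span from 127 samples before the first kept R peak to
#' 192 samples after the last one, so the pair is sample-aligned on the
#' normalized amplitude scale.
#'
#' @param record A raw [ecg_record()].
#' @param bcae A trained [build_bcae()] model.
#' @param recn Optional trained [build_recn()] model.
#' @return List: `original` (normalized preprocessed segment),
#'   `reconstructed` (stitched, same length, normalized scale), `stream`,
#'   `n_beats`, `bits_in`, `bits_out`.
#' @export
round_trip_record <- function(record, bcae, recn = NULL) {
  pre <- preprocess_record(record)
  r_idx <- detect_r_peaks(pre$record)
  beats <- segment_beats(pre$record, r_idx)
  stream <- compress_record(record, bcae, r_indices = r_idx)
  recon <- bcae_decode(bcae, stream$codes)
  if (!is.null(recn))
    recon <- compensate(recon, recn_predict(recn, stream$codes), recn$scale)
  stitched <- stitch_record(recon, stream$intervals)
  r <- beats$r_index
  span <- (r[1] - 127L):(r[length(r)] + 192L)
  bits <- stream_bits(stream)
  list(original = pre$record$samples[span], reconstructed = stitched,
       stream = stream, n_beats = stream$beat_count,
       bits_in = bits$bits_in, bits_out = bits$bits_out)
}

#' Per-record and aggregate compression metrics
#'
#' Computes CR, PRD, PRDN, RMS, SNR and QS per record on the concatenated
#' stitched signals (normalized amplitude scale), plus an aggregate row that
#' is the arithmetic mean of the per-record values — including QS, which is
#' averaged per record rather than recomputed as CR over mean PRD.
#'
#' @param pairs Named list of [round_trip_record()] results (one per
#'   record).
#' @return A data.frame with one row per record and a final `"average"`
#'   row.
#' @export
evaluate_compression <- function(pairs) {
  stopifnot(length(pairs) > 0L)
  if (is.null(names(pairs))) names(pairs) <- paste0("record", seq_along(pairs))
  rows <- lapply(names(pairs), function(id) {
    p <- pairs[[id]]
    if (length(p$original) != length(p$reconstructed))
      stop("record ", id, ": original and reconstruction lengths differ")
    pr <- prd(p$original, p$reconstructed)
    data.frame(record = id,
               cr = compression_ratio(p$bits_in, p$bits_out),
               prd = pr,
               prdn = prdn(p$original, p$reconstructed),
               rms = rms(p$original, p$reconstructed),
               snr = snr(p$original, p$reconstructed),
               qs = if (pr > 0) qs(compression_ratio(p$bits_in, p$bits_out), pr)
                    else NA_real_)
  })
  tab <- do.call(rbind, rows)
  agg <- data.frame(record = "average", cr = mean(tab$cr), prd = mean(tab$prd),
                    prdn = mean(tab$prdn), rms = mean(tab$rms),
                    snr = mean(tab$snr), qs = mean(tab$qs))
  rbind(tab, agg)
}
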