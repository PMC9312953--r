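#' Bandpass-filter an ECG record
#'
#' Removes baseline wander and high-frequency noise with a 4th-order
#' Butterworth bandpass applied forward and backward (zero phase), so R-peak
#' timing is not shifted before segmentation.
#'
#' @param record A [ecg_record()].
#' @param low,high Band edges in Hz.
#' @return The filtered [ecg_record()] (same length and sampling rate).
#' @export
bandpass_filter <- function(record, low = 0.5, high = 150) {
  stopifnot(inherits(record, "becg_record"))
  if (high >= record$fs / 2)
    stop("upper band edge must be below the Nyquist frequency (", record$fs / 2,
         " Hz)")
  bf <- signal::butter(2, c(low, high) / (record$fs / 2), type = "pass")
  # odd-reflection padding suppresses the long start-up transient of the
  # 0.5 Hz high-pass edge before the forward-backward pass
  x <- record$samples
  n <- length(x)
  pad <- min(n - 1L, as.integer(3 * record$fs))
  xp <- c(2 * x[1] - x[(pad + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - pad)])
  y <- signal::filtfilt(bf, xp)[pad + seq_len(n)]
  ecg_record(y, fs = record$fs, resolution_bits = record$resolution_bits,
             r_truth = record$r_truth, record_id = record$record_id,
             quantized = FALSE)
}

#' Max-min normalization
#'
#' Maps the record affinely onto \[0, 1\] and returns the parameters needed
#' to invert the mapping at reconstruction time.
#'
#' @param record A [ecg_record()].
#' @return A list with elements `record` (the normalized [ecg_record()]) and
#'   `params` (list with `min_value`, `max_value`).
#' @export
normalize_minmax <- function(record) {
  stopifnot(inherits(record, "becg_record"))
  rng <- range(record$samples)
  if (rng[1] == rng[2]) stop("cannot normalize a constant record")
  y <- (record$samples - rng[1]) / (rng[2] - rng[1])
  params <- structure(list(min_value = rng[1], max_value = rng[2]),
                      class = "becg_norm")
  rec <- ecg_record(y, fs = record$fs, resolution_bits = record$resolution_bits,
                    r_truth = record$r_truth, record_id = record$record_id,
                    quantized = FALSE)
  list(record = rec, params = params)
}

#' Invert max-min normalization
#'
#' @param x A numeric vector or [ecg_record()] on the normalized \[0, 1\]
#'   scale.
#' @param params Normalization parameters from [normalize_minmax()].
#' @return Same shape as `x`, on the original amplitude scale.
#' @export
denormalize <- function(x, params) {
  stopifnot(params$max_value > params$min_value)
  f <- function(v) v * (params$max_value - params$min_value) + params$min_value
  if (inherits(x, "becg_record")) {
    x$samples <- f(x$samples)
    x
  } else f(x)
}

#' Filter and normalize a raw record
#'
#' Convenience pipeline step: [bandpass_filter()] then [normalize_minmax()].
#'
#' @param record A [ecg_record()].
#' @param low,high Band edges in Hz.
#' @return A list with `record` (filtered, normalized) and `params`.
#' @export
preprocess_record <- function(record, low = 0.5, high = 150) {
  normalize_minmax(bandpass_filter(record, low, high))
}

#' Pan-Tompkins R-peak detection
#'
#' QRS detection by the Pan-Tompkins algorithm: 5-15 Hz bandpass,
#' differentiation, squaring, 150-ms moving-window integration, adaptive
#' signal/noise thresholds with a 200-ms refractory period and search-back
#' for missed beats. Detections are refined to the local extremum of the
#' bandpassed waveform so the returned indices land on the R sample.
#'
#' @param record A [ecg_record()] at least 2 s long.
#' @param refractory Minimum spacing between detections, in seconds.
#' @return Strictly increasing integer vector of R-peak indices (1-based);
#'   empty for a flat record.
#' @export
detect_r_peaks <- function(record, refractory = 0.2) {
  stopifnot(inherits(record, "becg_record"))
  fs <- record$fs
  x <- as.numeric(record$samples)
  n <- length(x)
  if (n < 2 * fs) stop("record too short for QRS detection (< 2 s)")
  refr <- max(1L, round(refractory * fs))

  bf <- signal::butter(2, c(5, 15) / (fs / 2), type = "pass")
  bp <- signal::filtfilt(bf, x)
  der <- c(bp[2] - bp[1], (bp[3:n] - bp[1:(n - 2)]) / 2, bp[n] - bp[n - 1])
  sq <- der^2
  w <- round(0.15 * fs)
  integ <- as.numeric(stats::filter(sq, rep(1 / w, w), sides = 2))
  integ[is.na(integ)] <- 0

  # candidate peaks: strict local maxima of the integration waveform
  d <- diff(integ)
  cand <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1L
  cand <- cand[integ[cand] > 0]
  if (length(cand) == 0L) return(integer(0))

  init <- integ[seq_len(min(n, 2 * fs))]
  spki <- 0.25 * max(init)
  npki <- 0.5 * mean(init)
  thr <- function() npki + 0.25 * (spki - npki)

  qrs <- integer(0)
  rr_hist <- numeric(0)
  for (p in cand) {
    if (length(qrs) > 0L && p - qrs[length(qrs)] < refr) next
    if (integ[p] > thr()) {
      spki <- 0.125 * integ[p] + 0.875 * spki
      if (length(qrs) > 0L) rr_hist <- c(rr_hist, p - qrs[length(qrs)])
      qrs <- c(qrs, p)
    } else {
      npki <- 0.125 * integ[p] + 0.875 * npki
      # search-back: accept a sub-threshold peak if a beat is overdue
      if (length(rr_hist) >= 2L && length(qrs) > 0L) {
        rr_avg <- mean(utils::tail(rr_hist, 8L))
        if (p - qrs[length(qrs)] > 1.66 * rr_avg && integ[p] > 0.5 * thr()) {
          spki <- 0.25 * integ[p] + 0.75 * spki
          rr_hist <- c(rr_hist, p - qrs[length(qrs)])
          qrs <- c(qrs, p)
        }
      }
    }
  }
  if (length(qrs) == 0L) return(integer(0))

  # refine to the R sample: local max of |bandpassed| then of the raw signal
  half <- as.integer(round(0.1 * fs))
  refine <- vapply(qrs, function(p) {
    lo <- max(1L, p - half); hi <- min(n, p + half)
    r1 <- lo + which.max(abs(bp[lo:hi])) - 1L
    lo2 <- max(1L, r1 - 8L); hi2 <- min(n, r1 + 8L)
    sgn <- sign(bp[r1])
    as.integer(lo2 + which.max(sgn * x[lo2:hi2]) - 1L)
  }, integer(1))
  refine <- sort(unique(refine))
  if (length(refine) > 1L) {
    keep <- c(TRUE, diff(refine) >= refr)
    refine <- refine[keep]
  }
  refine
}

#' Segment fixed 320-sample beats around R peaks
#'
#' Each beat spans 127 samples left of the R peak and 192 right of it
#' (127 + 192 + 1 = 320 samples, both ends inclusive). R peaks too close to
#' a record boundary are skipped.
#'
#' @param record A [ecg_record()] (normally filtered and normalized).
#' @param r_indices Integer vector of R-peak indices (1-based).
#' @return A `becg_beats` container: list with `samples` (320 x n matrix,
#'   one beat per column), `r_index`, `record_id`, `fs`.
#' @export
segment_beats <- function(record, r_indices) {
  stopifnot(inherits(record, "becg_record"))
  n <- length(record$samples)
  r_indices <- as.integer(sort(r_indices))
  keep <- r_indices >= 128L & r_indices + 192L <= n
  if (any(!keep))
    message(sum(!keep), " boundary beat(s) skipped in record ",
            record$record_id)
  r <- r_indices[keep]
  beats <- vapply(r, function(ri) record$samples[(ri - 127L):(ri + 192L)],
                  numeric(320L))
  beats <- matrix(beats, nrow = 320L)
  structure(list(samples = beats, r_index = r,
                 record_id = rep(record$record_id, length(r)),
                 fs = record$fs),
            class = "becg_beats")
}

#' @export
print.becg_beats <- function(x, ...) {
  cat(sprintf("<becg_beats: %d beats of 320 samples from %d record(s)>\n",
              ncol(x$samples), length(unique(x$record_id))))
  invisible(x)
}

#' Pool beats from several containers
#'
#' @param x List of `becg_beats` objects.
#' @return A single `becg_beats` container.
#' @export
bind_beats <- function(x) {
  stopifnot(length(x) > 0L, all(vapply(x, inherits, logical(1), "becg_beats")))
  structure(list(samples = do.call(cbind, lapply(x, `[[`, "samples")),
                 r_index = do.call(c, lapply(x, `[[`, "r_index")),
                 record_id = do.call(c, lapply(x, `[[`, "record_id")),
                 fs = x[[1]]$fs),
            class = "becg_beats")
}

#' Subset a beats container
#'
#' @param beats A `becg_beats` container.
#' @param idx Column (beat) indices to keep.
#' @return A `becg_beats` container.
#' @export
subset_beats <- function(beats, idx) {
  structure(list(samples = beats$samples[, idx, drop = FALSE],
                 r_index = beats$r_index[idx],
                 record_id = beats$record_id[idx], fs = beats$fs),
            class = "becg_beats")
}

#' Encode the gap between consecutive beat windows as a 10-bit interval code
#'
#' The interval is defined between consecutive 320-sample beat windows:
#' `gap = RR - beat_len`. A non-negative gap (the beat is delayed relative
#' to the end of the previous window) gets flag 0; an overlap gets flag 1.
#' The 9-bit magnitude limits encodable gaps to 511 samples either way.
#'
#' @param rr RR interval(s) in samples (distance between consecutive R
#'   peaks).
#' @param beat_len Beat window length (320).
#' @return A data.frame with integer columns `flag` and `magnitude`.
#' @export
encode_interval <- function(rr, beat_len = 320L) {
  gap <- as.integer(round(rr)) - as.integer(beat_len)
  if (any(abs(gap) > 511L))
    stop("interval of ", max(abs(gap)),
         " samples exceeds 9-bit interval range (511)")
  data.frame(flag = as.integer(gap < 0L), magnitude = abs(gap))
}

#' Decode an interval code to a signed gap
#'
#' @param code A data.frame with columns `flag`, `magnitude` (from
#'   [encode_interval()]).
#' @return Integer vector of signed gaps in samples (positive = delay,
#'   negative = overlap).
#' @export
decode_interval <- function(code) {
  stopifnot(all(code$flag %in% c(0L, 1L)),
            all(code$magnitude >= 0L & code$magnitude <= 511L))
  as.integer(ifelse(code$flag == 0L, code$magnitude, -code$magnitude))
}

#' Interval codes for a sequence of segmented beats
#'
#' The first beat has no predecessor and is assigned flag 0, magnitude 0.
#'
#' @param r_index Integer vector of kept R-peak indices.
#' @param beat_len Beat window length.
#' @return A data.frame of interval codes, one row per beat.
#' @export
beat_intervals <- function(r_index, beat_len = 320L) {
  if (length(r_index) == 0L)
    return(data.frame(flag = integer(0), magnitude = integer(0)))
  first <- data.frame(flag = 0L, magnitude = 0L)
  if (length(r_index) == 1L) return(first)
  rbind(first, encode_interval(diff(r_index), beat_len))
}
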