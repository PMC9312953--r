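#' Morphology parameters for the synthetic beat model
#'
#' A heartbeat is modelled as the sum of five Gaussian bumps, one per wave
#' (P, Q, R, S, T), each with a centre offset relative to the R peak (in
#' samples), a dimensionless amplitude, and a width (standard deviation in
#' samples). The R wave must have the strictly largest absolute amplitude so
#' that the R peak anchors the beat window.
#'
#' @param wave_centers Named numeric vector of 5 offsets (samples, relative
#'   to R; the R entry must be 0).
#' @param wave_amplitudes Named numeric vector of 5 amplitudes.
#' @param wave_widths Named numeric vector of 5 standard deviations
#'   (samples, all > 0).
#' @return An object of class `becg_morphology`.
#' @export
morphology_params <- function(wave_centers, wave_amplitudes, wave_widths) {
  waves <- c("P", "Q", "R", "S", "T")
  for (v in list(wave_centers, wave_amplitudes, wave_widths))
    if (length(v) != 5L) stop("each morphology field needs 5 values (P,Q,R,S,T)")
  wave_centers <- stats::setNames(as.numeric(wave_centers), waves)
  wave_amplitudes <- stats::setNames(as.numeric(wave_amplitudes), waves)
  wave_widths <- stats::setNames(as.numeric(wave_widths), waves)
  if (any(wave_widths <= 0)) stop("wave widths must be > 0")
  if (wave_centers[["R"]] != 0) stop("the R wave centre must be 0")
  if (any(abs(wave_amplitudes[-3L]) >= abs(wave_amplitudes[["R"]])))
    stop("the R wave must have the strictly largest absolute amplitude")
  structure(list(wave_centers = wave_centers,
                 wave_amplitudes = wave_amplitudes,
                 wave_widths = wave_widths),
            class = "becg_morphology")
}

#' Named morphology presets
#'
#' Three presets with distinct QRS and T-wave shapes, standing in for the
#' morphological variety of real single-lead recordings.
#'
#' @param name One of `"normal"`, `"tall_t"`, `"wide_qrs"`.
#' @return A [morphology_params()] object.
#' @export
morphology_preset <- function(name = c("normal", "tall_t", "wide_qrs")) {
  name <- match.arg(name)
  switch(name,
    normal = morphology_params(
      wave_centers = c(P = -60, Q = -12, R = 0, S = 12, T = 75),
      wave_amplitudes = c(P = 0.17, Q = -0.12, R = 1.00, S = -0.22, T = 0.32),
      wave_widths = c(P = 11, Q = 3, R = 4.5, S = 4, T = 19)),
    tall_t = morphology_params(
      wave_centers = c(P = -65, Q = -10, R = 0, S = 11, T = 88),
      wave_amplitudes = c(P = 0.12, Q = -0.08, R = 1.00, S = -0.15, T = 0.62),
      wave_widths = c(P = 10, Q = 2.5, R = 4, S = 3.5, T = 26)),
    wide_qrs = morphology_params(
      wave_centers = c(P = -70, Q = -18, R = 0, S = 20, T = 95),
      wave_amplitudes = c(P = 0.08, Q = -0.25, R = 1.00, S = -0.45, T = -0.28),
      wave_widths = c(P = 10, Q = 7, R = 9, S = 8, T = 22)))
}

#' Rhythm parameters for the synthetic record generator
#'
#' RR intervals are drawn from a normal distribution truncated to the
#' interval-encodable range (`beat length +/- 511` samples, floored at 1).
#' The rhythm presets mirror the mean RR intervals of the three
#' variable-rhythm reference records (286.05, 422.85 and 327.02 samples).
#'
#' @param rr_mean Mean RR interval, samples.
#' @param rr_sd RR standard deviation, samples.
#' @param n_beats Number of beats (>= 1).
#' @param noise_sd Gaussian noise standard deviation, relative to unit R
#'   amplitude.
#' @param baseline_amp Baseline-wander amplitude, relative units.
#' @param baseline_freq Baseline-wander frequency, Hz.
#' @return An object of class `becg_rhythm`.
#' @export
rhythm_params <- function(rr_mean = 327.02, rr_sd = 15, n_beats = 60,
                          noise_sd = 0.02, baseline_amp = 0.08,
                          baseline_freq = 0.25) {
  if (n_beats < 1) stop("n_beats must be >= 1")
  if (rr_mean - 3 * rr_sd <= 0) stop("rr_mean - 3*rr_sd must be positive")
  if (abs(rr_mean - 320) > 511)
    stop("rr_mean outside the interval-encodable range (320 +/- 511 samples)")
  structure(list(rr_mean = rr_mean, rr_sd = rr_sd, n_beats = as.integer(n_beats),
                 noise_sd = noise_sd, baseline_amp = baseline_amp,
                 baseline_freq = baseline_freq),
            class = "becg_rhythm")
}

#' Rhythm presets mirroring the three variable-rhythm reference records
#'
#' @param name One of `"overlap"` (mean RR 286.05, beats overlap the
#'   320-sample window), `"gap"` (422.85, beats leave a gap), `"near"`
#'   (327.02, near-abutting).
#' @param ... Passed on to [rhythm_params()] to override other fields.
#' @return A [rhythm_params()] object.
#' @export
rhythm_preset <- function(name = c("near", "overlap", "gap"), ...) {
  name <- match.arg(name)
  rr <- switch(name, overlap = 286.05, gap = 422.85, near = 327.02)
  rhythm_params(rr_mean = rr, ...)
}

#' Construct an ECG record object
#'
#' @param samples Numeric vector of samples (ADC integer counts when
#'   `quantized`, arbitrary units otherwise).
#' @param fs Sampling frequency, Hz.
#' @param resolution_bits ADC resolution in bits.
#' @param r_truth Optional integer vector of ground-truth R-peak sample
#'   indices (1-based).
#' @param record_id Identifier string.
#' @param quantized Logical; whether `samples` are ADC integer counts.
#' @return An object of class `becg_record`.
#' @export
ecg_record <- function(samples, fs = 360, resolution_bits = 11,
                       r_truth = NULL, record_id = "record", quantized = FALSE) {
  if (fs <= 0) stop("fs must be positive")
  samples <- as.numeric(samples)
  if (quantized) {
    top <- 2^resolution_bits - 1
    if (any(samples < 0 | samples > top))
      stop("quantized samples must lie in [0, ", top, "]")
  }
  structure(list(samples = samples, fs = fs,
                 resolution_bits = as.integer(resolution_bits),
                 r_truth = if (!is.null(r_truth)) as.integer(r_truth),
                 record_id = record_id, quantized = quantized),
            class = "becg_record")
}

#' @export
print.becg_record <- function(x, ...) {
  cat(sprintf("<becg_record '%s': %d samples @ %g Hz, %d-bit%s%s>\n",
              x$record_id, length(x$samples), x$fs, x$resolution_bits,
              if (x$quantized) ", quantized" else "",
              if (!is.null(x$r_truth))
                sprintf(", %d annotated R peaks", length(x$r_truth)) else ""))
  invisible(x)
}

#' Generate one beat template from morphology parameters
#'
#' Sums the five Gaussian waves onto a window of `length` samples with the R
#' wave centred at `r_pos`.
#'
#' @param morph A [morphology_params()] object.
#' @param length Template length in samples.
#' @param r_pos Index of the R position within the template (1-based).
#' @return Numeric vector of `length` samples.
#' @export
generate_beat_template <- function(morph, length = 320L, r_pos = 128L) {
  stopifnot(inherits(morph, "becg_morphology"))
  t <- seq_len(length) - r_pos  # offsets relative to R
  y <- numeric(length)
  for (w in names(morph$wave_centers)) {
    ctr <- morph$wave_centers[[w]]
    wid <- morph$wave_widths[[w]]
    if (r_pos + ctr - 3 * wid < 1 || r_pos + ctr + 3 * wid > length)
      stop(sprintf("wave %s extends beyond the template (centre %g, width %g)",
                   w, ctr, wid))
    y <- y + morph$wave_amplitudes[[w]] * exp(-((t - ctr)^2) / (2 * wid^2))
  }
  y
}

# Draw RR intervals from a truncated normal over the encodable range.
draw_rr <- function(n, rr_mean, rr_sd, beat_len = 320L, max_tries = 100L) {
  lo <- max(1, beat_len - 511)
  hi <- beat_len + 511
  out <- numeric(n)
  for (i in seq_len(n)) {
    for (k in seq_len(max_tries)) {
      r <- stats::rnorm(1L, rr_mean, rr_sd)
      if (r >= lo && r <= hi) { out[i] <- r; break }
      if (k == max_tries)
        stop("could not draw an interval-encodable RR after ", max_tries,
             " tries")
    }
  }
  round(out)
}

#' Generate a synthetic single-lead ECG record
#'
#' Places `n_beats` copies of the beat template at RR spacings drawn from a
#' truncated normal distribution, adds sinusoidal baseline wander and
#' Gaussian noise, and quantizes the result to the ADC resolution. The
#' ground-truth R indices are stored in the record. Identical arguments and
#' seed give a bit-identical record.
#'
#' @param morph A [morphology_params()] object.
#' @param rhythm A [rhythm_params()] object.
#' @param seed Integer seed.
#' @param fs Sampling frequency, Hz.
#' @param resolution_bits ADC resolution in bits.
#' @param record_id Identifier string.
#' @return A quantized [ecg_record()] with `r_truth` populated.
#' @export
generate_ecg <- function(morph = morphology_preset("normal"),
                         rhythm = rhythm_params(), seed = 1L, fs = 360,
                         resolution_bits = 11L, record_id = "synth") {
  stopifnot(inherits(morph, "becg_morphology"), inherits(rhythm, "becg_rhythm"))
  with_seed(seed, {
    n <- rhythm$n_beats
    rr <- if (n > 1L) draw_rr(n - 1L, rhythm$rr_mean, rhythm$rr_sd) else integer(0)
    margin <- 192L
    r_idx <- as.integer(cumsum(c(128L + margin, rr)))
    len <- r_idx[n] + 192L + margin
    sig <- numeric(len)
    template <- generate_beat_template(morph, length = 320L, r_pos = 128L)
    for (r in r_idx) {
      span <- (r - 127L):(r + 192L)
      sig[span] <- sig[span] + template
    }
    if (rhythm$baseline_amp > 0) {
      phase <- stats::runif(1L, 0, 2 * pi)
      sig <- sig + rhythm$baseline_amp *
        sin(2 * pi * rhythm$baseline_freq * seq_len(len) / fs + phase)
    }
    if (rhythm$noise_sd > 0)
      sig <- sig + stats::rnorm(len, 0, rhythm$noise_sd)
    top <- 2^resolution_bits - 1
    rng <- range(sig)
    if (rng[1] == rng[2]) stop("degenerate (constant) synthetic signal")
    q <- round((sig - rng[1]) / (rng[2] - rng[1]) * top)
    ecg_record(q, fs = fs, resolution_bits = resolution_bits,
               r_truth = r_idx, record_id = record_id, quantized = TRUE)
  })
}

#' Generate a multi-preset synthetic beat corpus
#'
#' Convenience wrapper producing one record per morphology preset and
#' rhythm preset pair, preprocessing each and pooling the segmented beats.
#' Used for reduced-scale training runs and in the test-suite.
#'
#' @param beats_per_record Approximate beats contributed by each of the three
#'   preset records.
#' @param seed Integer seed.
#' @param noise_sd,baseline_amp Passed to [rhythm_params()].
#' @return A `becg_beats` container (see [segment_beats()]).
#' @export
synthetic_corpus <- function(beats_per_record = 500L, seed = 1L,
                             noise_sd = 0.02, baseline_amp = 0.08) {
  presets <- c("normal", "tall_t", "wide_qrs")
  rhythms <- c("overlap", "gap", "near")
  all <- vector("list", length(presets))
  for (i in seq_along(presets)) {
    rec <- generate_ecg(
      morph = morphology_preset(presets[i]),
      rhythm = rhythm_preset(rhythms[i], n_beats = beats_per_record + 2L,
                             noise_sd = noise_sd, baseline_amp = baseline_amp),
      seed = seed + i, record_id = presets[i])
    pre <- preprocess_record(rec)
    peaks <- detect_r_peaks(pre$record)
    all[[i]] <- segment_beats(pre$record, peaks)
  }
  bind_beats(all)
}
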