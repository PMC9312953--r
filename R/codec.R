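int_to_bits <- function(x, nbits) {
  vapply(x, function(v) as.integer(bitwAnd(bitwShiftR(v, (nbits - 1L):0L), 1L)),
         integer(nbits))
}

bits_to_int <- function(bits) {
  nbits <- nrow(bits)
  as.integer(colSums(bits * 2^((nbits - 1L):0L)))
}

#' Pack an interval code and a binary code into one 30-bit unit
#'
#' Bit layout, most significant first: 1 flag bit, 9 magnitude bits
#' (MSB-first), then the 20 code bits in encoder-output order. The layout is
#' fixed so that streams are portable across implementations.
#'
#' @param interval One-row data.frame with `flag`, `magnitude` (or a
#'   multi-row data.frame for several packs).
#' @param code Integer vector of 20 bits (or `20 x n` matrix).
#' @return Integer `30 x n` matrix of bits (a vector for a single pack is
#'   returned as a 30 x 1 matrix).
#' @export
pack_unit <- function(interval, code) {
  if (is.null(dim(code))) code <- matrix(code, ncol = nrow(interval))
  stopifnot(nrow(code) == 20L, ncol(code) == nrow(interval),
            all(code %in% c(0L, 1L)),
            all(interval$flag %in% c(0L, 1L)),
            all(interval$magnitude >= 0L & interval$magnitude <= 511L))
  rbind(matrix(as.integer(interval$flag), 1L),
        int_to_bits(interval$magnitude, 9L),
        matrix(as.integer(code), 20L))
}

#' Unpack 30-bit units into interval codes and binary codes
#'
#' @param bits Integer `30 x n` matrix of bits (inverse of [pack_unit()]).
#' @return List with `interval` (data.frame `flag`, `magnitude`) and `code`
#'   (`20 x n` integer matrix).
#' @export
unpack_unit <- function(bits) {
  if (is.null(dim(bits))) bits <- matrix(bits, ncol = 1L)
  stopifnot(nrow(bits) == 30L, all(bits %in% c(0L, 1L)))
  list(interval = data.frame(flag = as.integer(bits[1L, ]),
                             magnitude = bits_to_int(bits[2:10, , drop = FALSE])),
       code = matrix(as.integer(bits[11:30, , drop = FALSE]), nrow = 20L))
}

#' Construct a compressed-stream object
#'
#' In-memory representation of a compressed record: a small header
#' (sampling rate, ADC resolution, beat count, per-record normalization
#' parameters) and one 30-bit pack per beat in temporal order.
#'
#' @param intervals Data.frame of interval codes (one row per beat).
#' @param codes `20 x n` matrix of binary codes.
#' @param fs Sampling rate, Hz.
#' @param resolution_bits ADC resolution of the source record.
#' @param norm_params Normalization parameters of the source record.
#' @param record_id Identifier string.
#' @return An object of class `becg_stream`.
#' @export
becg_stream <- function(intervals, codes, fs = 360, resolution_bits = 11L,
                        norm_params = NULL, record_id = "record") {
  if (is.null(dim(codes))) codes <- matrix(codes, nrow = 20L)
  stopifnot(nrow(intervals) == ncol(codes))
  structure(list(fs = fs, resolution_bits = as.integer(resolution_bits),
                 beat_count = nrow(intervals), intervals = intervals,
                 codes = codes, norm_params = norm_params,
                 record_id = record_id, version = 1L),
            class = "becg_stream")
}

#' @export
print.becg_stream <- function(x, ...) {
  cat(sprintf("<becg_stream '%s': %d beats, %d payload bits (%d-bit packs)>\n",
              x$record_id, x$beat_count, 30L * x$beat_count, 30L))
  invisible(x)
}

#' Compress an ECG record
#'
#' Full compression pipeline: bandpass filter, max-min normalization,
#' Pan-Tompkins R-peak detection, 320-sample beat segmentation, interval
#' coding of the inter-beat gaps, and BCAE encoding of each beat into 20
#' binary bits. Each beat contributes one 30-bit pack; normalization
#' parameters travel once in the stream header.
#'
#' @param record A raw [ecg_record()].
#' @param bcae A trained [build_bcae()] model.
#' @param r_indices Optional pre-computed R-peak indices (skips detection).
#' @return A [becg_stream()].
#' @export
compress_record <- function(record, bcae, r_indices = NULL) {
  stopifnot(inherits(record, "becg_record"), inherits(bcae, "becg_bcae"))
  pre <- preprocess_record(record)
  if (is.null(r_indices)) r_indices <- detect_r_peaks(pre$record)
  beats <- segment_beats(pre$record, r_indices)
  n <- ncol(beats$samples)
  if (n == 0L)
    return(becg_stream(data.frame(flag = integer(0), magnitude = integer(0)),
                       matrix(integer(0), 20L, 0L), fs = record$fs,
                       resolution_bits = record$resolution_bits,
                       norm_params = pre$params, record_id = record$record_id))
  rr <- diff(beats$r_index)
  bad <- which(abs(rr - 320L) > 511L)
  if (length(bad) > 0L)
    stop("RR interval at beat ", bad[1] + 1L, " (", rr[bad[1]],
         " samples) is not interval-encodable")
  intervals <- beat_intervals(beats$r_index)
  codes <- bcae_encode(bcae, beats)
  becg_stream(intervals, codes, fs = record$fs,
              resolution_bits = record$resolution_bits,
              norm_params = pre$params, record_id = record$record_id)
}

#' Stitch reconstructed beats into a continuous signal
#'
#' Beats are placed sequentially. A positive gap (flag 0) of g samples is
#' filled by linear interpolation between the last sample of the previous
#' beat and the first sample of the next; an overlap (flag 1) of v samples
#' replaces the shared span with the elementwise mean of the two
#' overlapping segments.
#'
#' @param beats `320 x n` matrix of reconstructed beats.
#' @param intervals Data.frame of interval codes, one row per beat (the
#'   first row places the first beat and is ignored).
#' @return Numeric vector; its length obeys
#'   `320 + sum(320 + gap_k)` over beats 2..n.
#' @export
stitch_record <- function(beats, intervals) {
  if (is.null(dim(beats))) beats <- matrix(beats, nrow = 320L)
  n <- ncol(beats)
  if (n != nrow(intervals))
    stop("number of beats and interval codes differ")
  if (n == 0L) return(numeric(0))
  gaps <- decode_interval(intervals)
  out <- beats[, 1L]
  for (k in seq_len(n)[-1L]) {
    g <- gaps[k]
    beat <- beats[, k]
    if (g >= 0L) {
      if (g > 0L) {
        a <- out[length(out)]; b <- beat[1L]
        out <- c(out, a + seq_len(g) * (b - a) / (g + 1L))
      }
      out <- c(out, beat)
    } else {
      v <- -g
      if (v >= 320L) stop("overlap of ", v, " samples covers a whole beat")
      tail_idx <- (length(out) - v + 1L):length(out)
      out[tail_idx] <- (out[tail_idx] + beat[seq_len(v)]) / 2
      out <- c(out, beat[(v + 1L):320L])
    }
  }
  out
}

#' Decompress a stream into a continuous record
#'
#' Decodes every 20-bit code with the BCAE decoder, refines each beat with
#' the RECN residual (if supplied), stitches the beats with the interval
#' codes, and undoes the max-min normalization with the header parameters.
#'
#' @param stream A [becg_stream()].
#' @param bcae A trained [build_bcae()] model.
#' @param recn Optional trained [build_recn()] model.
#' @return A reconstructed [ecg_record()] (continuous, denormalized if the
#'   header carries normalization parameters).
#' @export
decompress_stream <- function(stream, bcae, recn = NULL) {
  stopifnot(inherits(stream, "becg_stream"), inherits(bcae, "becg_bcae"))
  if (stream$beat_count == 0L)
    return(ecg_record(numeric(0), fs = stream$fs,
                      resolution_bits = stream$resolution_bits,
                      record_id = stream$record_id))
  recon <- bcae_decode(bcae, stream$codes)
  if (!is.null(recn))
    recon <- compensate(recon, recn_predict(recn, stream$codes), recn$scale)
  sig <- stitch_record(recon, stream$intervals)
  if (!is.null(stream$norm_params))
    sig <- denormalize(sig, stream$norm_params)
  ecg_record(sig, fs = stream$fs, resolution_bits = stream$resolution_bits,
             record_id = stream$record_id)
}

#' Bit accounting for a compressed stream
#'
#' @param stream A [becg_stream()].
#' @return List with `bits_in` (raw beat samples x ADC bits), `bits_out`
#'   (30 bits per pack, header excluded) and `cr` (their ratio).
#' @export
stream_bits <- function(stream) {
  bits_in <- 320 * stream$resolution_bits * stream$beat_count
  bits_out <- 30 * stream$beat_count
  list(bits_in = bits_in, bits_out = bits_out,
       cr = if (bits_out > 0) bits_in / bits_out else NA_real_)
}

#' Write a compressed stream to a `.becg` file
#'
#' Binary layout: magic `"BECG"`, one version byte, little-endian header
#' (fs as double, resolution byte, beat count as 32-bit integer, the two
#' normalization doubles), then the bit-contiguous 30-bit packs padded with
#' zero bits to the final byte boundary only.
#'
#' @param stream A [becg_stream()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_becg <- function(stream, path) {
  stopifnot(inherits(stream, "becg_stream"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("BECG"), con)
  writeBin(as.raw(stream$version), con)
  writeBin(as.double(stream$fs), con, size = 8L, endian = "little")
  writeBin(as.raw(stream$resolution_bits), con)
  writeBin(as.integer(stream$beat_count), con, size = 4L, endian = "little")
  np <- stream$norm_params
  writeBin(as.double(c(if (is.null(np)) c(0, 1)
                       else c(np$min_value, np$max_value))),
           con, size = 8L, endian = "little")
  if (stream$beat_count > 0L) {
    bits <- as.integer(pack_unit(stream$intervals, stream$codes))
    pad <- (-length(bits)) %% 8L
    writeBin(packBits(as.raw(c(bits, integer(pad))), "raw"), con)
  }
  invisible(path)
}

#' Read a `.becg` compressed stream
#'
#' @param path File written by [write_becg()].
#' @return A [becg_stream()].
#' @export
read_becg <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 4L)
  if (!identical(rawToChar(magic), "BECG")) stop("not a .becg stream: ", path)
  version <- as.integer(readBin(con, "raw", 1L))
  if (version != 1L) stop("unknown .becg stream version: ", version)
  fs <- readBin(con, "double", 1L, size = 8L, endian = "little")
  res_bits <- as.integer(readBin(con, "raw", 1L))
  beat_count <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  np <- readBin(con, "double", 2L, size = 8L, endian = "little")
  norm <- structure(list(min_value = np[1], max_value = np[2]),
                    class = "becg_norm")
  if (beat_count == 0L)
    return(becg_stream(data.frame(flag = integer(0), magnitude = integer(0)),
                       matrix(integer(0), 20L, 0L), fs = fs,
                       resolution_bits = res_bits, norm_params = norm,
                       record_id = basename(path)))
  nbytes <- ceiling(30 * beat_count / 8)
  payload <- readBin(con, "raw", nbytes)
  avail_packs <- floor(length(payload) * 8 / 30)
  if (length(payload) < nbytes)
    stop("truncated payload: stream ends inside pack ", avail_packs + 1L,
         " of ", beat_count)
  bits <- as.integer(rawToBits(payload))[seq_len(30L * beat_count)]
  up <- unpack_unit(matrix(bits, nrow = 30L))
  becg_stream(up$interval, up$code, fs = fs, resolution_bits = res_bits,
              norm_params = norm, record_id = basename(path))
}
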