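#' Read a WFDB record
#'
#' Minimal reader for WFDB header (`.hea`) plus signal (`.dat`) files in
#' formats 16 (little-endian 16-bit) and 212 (packed 12-bit pairs), the
#' formats used by the reference arrhythmia database. Returns one channel
#' as raw ADC counts; sampling rate and ADC resolution are taken from the
#' header. R-peak annotations are loaded from a plain-text sidecar
#' `<record>.anno.csv` (one sample index per line) when present.
#'
#' @param path Record path prefix (with or without the `.hea` extension).
#' @param channel 1-based channel selector.
#' @return A [ecg_record()] with raw ADC sample values.
#' @export
read_wfdb <- function(path, channel = 1L) {
  prefix <- sub("\\.hea$", "", path)
  hea <- paste0(prefix, ".hea")
  if (!file.exists(hea)) stop("WFDB header not found: ", hea)
  lines <- readLines(hea, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  head_f <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  nsig <- as.integer(head_f[2])
  fs <- if (length(head_f) >= 3L) as.numeric(sub("/.*$", "", head_f[3])) else 250
  nsamp <- if (length(head_f) >= 4L) as.integer(head_f[4]) else NA_integer_
  if (is.na(nsig) || nsig < 1L) stop("malformed WFDB header: ", hea)
  if (channel < 1L || channel > nsig)
    stop("channel ", channel, " not in record (", nsig, " signals)")
  sig_f <- strsplit(trimws(lines[1L + channel]), "\\s+")[[1]]
  fname <- sig_f[1]
  fmt <- as.integer(sub("x.*$|:.*$|\\+.*$", "", sig_f[2]))
  res_bits <- if (length(sig_f) >= 4L && !is.na(as.integer(sig_f[4])))
    as.integer(sig_f[4]) else 12L
  datpath <- file.path(dirname(hea), fname)
  if (!file.exists(datpath)) stop("WFDB signal file not found: ", datpath)
  raw <- readBin(datpath, "raw", file.info(datpath)$size)
  vals <- switch(as.character(fmt),
    "16" = readBin(raw, "integer", length(raw) %/% 2L, size = 2L,
                   signed = TRUE, endian = "little"),
    "212" = decode_fmt212(raw),
    stop("unsupported WFDB signal format: ", fmt))
  # channels are interleaved sample frame by sample frame
  x <- vals[seq(channel, length(vals), by = nsig)]
  if (!is.na(nsamp) && length(x) >= nsamp) x <- x[seq_len(nsamp)]
  anno <- paste0(prefix, ".anno.csv")
  r_truth <- if (file.exists(anno)) {
    v <- utils::read.csv(anno)
    as.integer(v[[1]])
  } else NULL
  rec <- ecg_record(x, fs = fs, resolution_bits = res_bits, r_truth = r_truth,
                    record_id = basename(prefix), quantized = FALSE)
  rec
}

decode_fmt212 <- function(raw) {
  n3 <- (length(raw) %/% 3L) * 3L
  b <- as.integer(raw[seq_len(n3)])
  b1 <- b[seq(1L, n3, 3L)]; b2 <- b[seq(2L, n3, 3L)]; b3 <- b[seq(3L, n3, 3L)]
  s1 <- b1 + bitwShiftL(bitwAnd(b2, 0x0FL), 8L)
  s2 <- b3 + bitwShiftL(bitwShiftR(b2, 4L), 8L)
  v <- as.vector(rbind(s1, s2))
  ifelse(v >= 2048L, v - 4096L, v)
}

#' Write an ECG record as a WFDB record
#'
#' Writes a `.hea` header and a format-16 `.dat` signal file, plus a
#' plain-text annotation sidecar `<record>.anno.csv` with the R-peak
#' indices when the record carries them. Samples are rounded to integers.
#'
#' @param record A [ecg_record()] (normally quantized).
#' @param path Output path prefix (no extension).
#' @return `path`, invisibly.
#' @export
write_wfdb <- function(record, path) {
  stopifnot(inherits(record, "becg_record"))
  x <- as.integer(round(record$samples))
  if (any(x < -32768L | x > 32767L)) stop("samples out of 16-bit range")
  name <- basename(path)
  writeLines(c(sprintf("%s 1 %g %d", name, record$fs, length(x)),
               sprintf("%s.dat 16 200 %d 0 %d 0 0 ECG", name,
                       record$resolution_bits,
                       if (length(x)) x[1] else 0L)),
             paste0(path, ".hea"))
  con <- file(paste0(path, ".dat"), "wb")
  writeBin(x, con, size = 2L, endian = "little")
  close(con)
  if (!is.null(record$r_truth))
    utils::write.csv(data.frame(sample = record$r_truth),
                     paste0(path, ".anno.csv"), row.names = FALSE)
  invisible(path)
}

#' Read an ECG signal from a one-sample-per-line CSV file
#'
#' @param path CSV path (single unnamed column, no header).
#' @param fs Sampling rate, Hz.
#' @param resolution_bits ADC resolution.
#' @param record_id Identifier.
#' @return A [ecg_record()].
#' @export
read_ecg_csv <- function(path, fs = 360, resolution_bits = 11L,
                         record_id = NULL) {
  x <- scan(path, what = numeric(), quiet = TRUE)
  ecg_record(x, fs = fs, resolution_bits = resolution_bits,
             record_id = record_id %||% basename(path))
}

#' Write an ECG signal as a one-sample-per-line CSV file
#'
#' @param record A [ecg_record()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ecg_csv <- function(record, path) {
  stopifnot(inherits(record, "becg_record"))
  writeLines(format(record$samples, trim = TRUE, scientific = FALSE), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
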