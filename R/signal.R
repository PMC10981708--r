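#' Construct a uniformly sampled signal
#'
#' The basic waveform container used throughout the package: a numeric
#' vector of samples together with its sampling rate. Heart-sound (PCG)
#' recordings are represented this way from WAV ingestion through
#' preprocessing to time-frequency analysis.
#'
#' @param samples Numeric vector of samples (normalized units). Must be
#'   finite and of length at least 2.
#' @param fs Sampling rate in Hz (positive scalar).
#' @return An object of class `pcg_signal` with elements `samples`, `fs`
#'   and `n_samples`.
#' @examples
#' s <- pcg_signal(sin(2 * pi * 5 * seq(0, 1, by = 1 / 100)), fs = 100)
#' s
#' @export
pcg_signal <- function(samples, fs) {
  samples <- as.double(samples)
  if (length(samples) < 2L) {
    stop("a signal needs at least 2 samples, got ", length(samples))
  }
  if (!all(is.finite(samples))) stop("signal samples must all be finite")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("'fs' must be a positive finite scalar (Hz)")
  }
  structure(
    list(samples = samples, fs = as.double(fs), n_samples = length(samples)),
    class = "pcg_signal"
  )
}

#' @export
print.pcg_signal <- function(x, ...) {
  cat(sprintf(
    "<pcg_signal> %d samples @ %g Hz (%.3f s), range [%.4g, %.4g]\n",
    x$n_samples, x$fs, x$n_samples / x$fs,
    min(x$samples), max(x$samples)
  ))
  invisible(x)
}

#' @export
length.pcg_signal <- function(x) x$n_samples

is_signal <- function(x) inherits(x, "pcg_signal")

assert_signal <- function(x) {
  if (!is_signal(x)) stop("expected a 'pcg_signal' object")
  invisible(x)
}

#' Duration of a signal in seconds
#' @param signal A [pcg_signal()].
#' @return Length in seconds.
#' @export
signal_duration <- function(signal) {
  assert_signal(signal)
  signal$n_samples / signal$fs
}

# ---- minimal mono PCM WAV codec -------------------------------------------
# A self-contained 16-bit mono PCM RIFF/WAVE reader and writer. Samples map
# to [-1, 1] via symmetric /32767 scaling so that signals already on the
# 16-bit grid round-trip exactly.

#' Write a signal to a mono 16-bit PCM WAV file
#'
#' Samples are clipped to \[-1, 1\] and quantized to 16-bit PCM
#' (`round(x * 32767)`).
#'
#' @param signal A [pcg_signal()] with samples in (approximately) \[-1, 1\].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(signal, path) {
  assert_signal(signal)
  x <- pmax(-1, pmin(1, signal$samples))
  pcm <- as.integer(round(x * 32767))
  n <- length(pcm)
  fs <- as.integer(round(signal$fs))
  con <- file(path, "wb")
  on.exit(close(con))
  data_bytes <- 2L * n
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")       # fmt chunk size
  writeBin(1L, con, size = 2, endian = "little")        # PCM
  writeBin(1L, con, size = 2, endian = "little")        # mono
  writeBin(fs, con, size = 4, endian = "little")
  writeBin(fs * 2L, con, size = 4, endian = "little")   # byte rate
  writeBin(2L, con, size = 2, endian = "little")        # block align
  writeBin(16L, con, size = 2, endian = "little")       # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(data_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a mono 16-bit PCM WAV file
#'
#' @param path Path to a mono, 16-bit PCM WAV file (the format this package
#'   emits; compressed or multi-channel WAVs are rejected).
#' @return A [pcg_signal()] with samples scaled by 1/32767 into \[-1, 1\].
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  readBin(con, "integer", size = 4, endian = "little")
  wave <- readChar(con, 4)
  if (!identical(riff, "RIFF") || !identical(wave, "WAVE")) {
    stop("not a RIFF/WAVE file: ", path)
  }
  fs <- NA_integer_
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0L || nchar(id) < 4L) stop("no 'data' chunk in ", path)
    size <- readBin(con, "integer", size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", n = 2, size = 2, endian = "little")
      if (fmt[1] != 1L) stop("only PCM WAV supported (format tag ", fmt[1], ")")
      if (fmt[2] != 1L) stop("only mono WAV supported (", fmt[2], " channels)")
      fs <- readBin(con, "integer", size = 4, endian = "little")
      readBin(con, "integer", size = 4, endian = "little") # byte rate
      readBin(con, "integer", size = 2, endian = "little") # block align
      bits <- readBin(con, "integer", size = 2, endian = "little")
      if (bits != 16L) stop("only 16-bit PCM supported (got ", bits, ")")
      if (size > 16L) readBin(con, "raw", n = size - 16L)
    } else if (identical(id, "data")) {
      pcm <- readBin(con, "integer",
        n = size %/% 2L, size = 2,
        signed = TRUE, endian = "little"
      )
      return(pcg_signal(pcm / 32767, fs = fs))
    } else {
      readBin(con, "raw", n = size + (size %% 2L))
    }
  }
}
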