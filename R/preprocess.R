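#' Preprocessing configuration
#'
#' Defaults follow the pipeline's operating point: 12.5 s records at
#' 1000 Hz, symmetric min-max normalization into \[-1, 1\].
#'
#' @param target_duration_s Fixed record duration in seconds (default 12.5).
#' @param target_fs Target sampling rate in Hz (default 1000).
#' @param normalization `"minmax_sym"` (map min to -1 and max to +1, the
#'   default) or `"zscore"` (zero mean, unit variance).
#' @return A `pcg_preprocess_config` list.
#' @export
preprocess_config <- function(target_duration_s = 12.5, target_fs = 1000,
                              normalization = c("minmax_sym", "zscore")) {
  normalization <- match.arg(normalization)
  if (target_duration_s <= 0) stop("'target_duration_s' must be positive")
  if (target_fs <= 0) stop("'target_fs' must be positive")
  structure(
    list(
      target_duration_s = target_duration_s,
      target_fs = target_fs,
      normalization = normalization
    ),
    class = "pcg_preprocess_config"
  )
}

# Zero-phase FIR low-pass: symmetric (linear-phase) Hamming-window FIR from
# signal::fir1, applied as a single centred convolution after edge-replication
# padding. Coefficients are renormalized to unit DC gain so constants pass
# through unchanged.
lowpass_zerophase <- function(x, w_cut, n_taps = 63L) {
  if (n_taps %% 2L == 0L) n_taps <- n_taps + 1L
  h <- signal::fir1(n_taps - 1L, w_cut, type = "low")
  h <- h / sum(h)
  half <- (n_taps - 1L) %/% 2L
  len <- length(x)
  padded <- c(rep(x[1L], half), x, rep(x[len], half))
  # linear convolution via FFT at a 2-3-5-smooth length
  L <- length(padded)
  M <- stats::nextn(L + n_taps, c(2L, 3L, 5L))
  conv <- Re(stats::fft(
    stats::fft(c(padded, rep(0, M - L))) *
      stats::fft(c(h, rep(0, M - n_taps))),
    inverse = TRUE
  )) / M
  conv[(2L * half + 1L):(2L * half + len)]
}

#' Resample a signal to a lower rate
#'
#' Applies an anti-aliasing low-pass filter (zero-phase FIR with cutoff at
#' 90% of the target Nyquist) and then interpolates onto the target sample
#' grid. Only down-sampling is supported; the pipeline never needs to
#' up-sample. Output length is exactly `round(N * target_fs / fs)`.
#'
#' @param signal A [pcg_signal()].
#' @param target_fs Target rate in Hz, `<= signal$fs`.
#' @return A [pcg_signal()] at `target_fs`.
#' @export
pcg_resample <- function(signal, target_fs) {
  assert_signal(signal)
  if (target_fs <= 0) stop("'target_fs' must be positive")
  if (target_fs > signal$fs) {
    stop(
      "up-sampling is not supported (requested ", target_fs,
      " Hz from ", signal$fs, " Hz)"
    )
  }
  if (target_fs == signal$fs) return(signal)
  n_out <- as.integer(round(signal$n_samples * target_fs / signal$fs))
  if (n_out < 2L) stop("signal too short to resample to ", target_fs, " Hz")
  w_cut <- 0.9 * target_fs / signal$fs # fraction of source Nyquist
  y <- lowpass_zerophase(signal$samples, w_cut)
  t_out <- (seq_len(n_out) - 1L) / target_fs
  t_in <- (seq_len(signal$n_samples) - 1L) / signal$fs
  out <- stats::approx(t_in, y, xout = t_out, rule = 2)$y
  pcg_signal(out, fs = target_fs)
}

#' Force a signal to a fixed duration
#'
#' Longer records are truncated to the first `target_duration_s` seconds;
#' shorter records are tiled end-to-end (no crossfade) and truncated so the
#' output is exactly `round(target_duration_s * fs)` samples.
#'
#' @param signal A [pcg_signal()].
#' @param target_duration_s Target duration in seconds.
#' @return A [pcg_signal()] of exactly the target length at the same rate.
#' @export
fix_duration <- function(signal, target_duration_s = 12.5) {
  assert_signal(signal)
  if (target_duration_s <= 0) stop("'target_duration_s' must be positive")
  n_target <- as.integer(round(target_duration_s * signal$fs))
  if (n_target == signal$n_samples) return(signal)
  pcg_signal(rep_len(signal$samples, n_target), fs = signal$fs)
}

#' Normalize a signal's amplitude
#'
#' `minmax_sym` maps the minimum to -1 and the maximum to +1 linearly
#' (the "normalized units" scale); a constant signal degenerates to all
#' zeros. `zscore` maps to zero mean and unit (sample) standard deviation.
#'
#' @param signal A [pcg_signal()].
#' @param mode `"minmax_sym"` or `"zscore"`.
#' @return A normalized [pcg_signal()].
#' @export
normalize_signal <- function(signal, mode = c("minmax_sym", "zscore")) {
  assert_signal(signal)
  mode <- match.arg(mode)
  x <- signal$samples
  if (mode == "minmax_sym") {
    rng <- range(x)
    if (rng[2] == rng[1]) {
      return(pcg_signal(rep(0, length(x)), fs = signal$fs))
    }
    y <- 2 * (x - rng[1]) / (rng[2] - rng[1]) - 1
  } else {
    s <- stats::sd(x)
    if (s == 0) stop("zscore normalization undefined for a constant signal")
    y <- (x - mean(x)) / s
  }
  pcg_signal(y, fs = signal$fs)
}

#' Full preprocessing chain for one recording
#'
#' Resamples to the target rate, fixes the duration, then normalizes —
#' in that order, so that tiling never duplicates anti-aliasing boundary
#' artifacts.
#'
#' @param signal A raw [pcg_signal()] (e.g. from [read_wav()]).
#' @param config A [preprocess_config()].
#' @return A [pcg_signal()] of exactly
#'   `round(target_duration_s * target_fs)` samples at `target_fs`.
#' @examples
#' raw <- pcg_signal(rnorm(20000), fs = 4000)
#' out <- preprocess_signal(raw, preprocess_config())
#' out$n_samples # 12500
#' @export
preprocess_signal <- function(signal, config = preprocess_config()) {
  if (!inherits(config, "pcg_preprocess_config")) {
    stop("'config' must come from preprocess_config()")
  }
  s <- signal
  if (s$fs > config$target_fs) s <- pcg_resample(s, config$target_fs)
  s <- fix_duration(s, config$target_duration_s)
  normalize_signal(s, config$normalization)
}

# ---- cohort manifest -------------------------------------------------------

#' Read a cohort manifest
#'
#' The canonical interchange format: a CSV with columns `patient_id`,
#' `location` (AV/PV/TV/MV), `wav_path` (relative to the manifest's
#' directory or absolute), `murmur_label` (Present/Unknown/Absent) and
#' `outcome_label` (Normal/Abnormal); one row per recording.
#'
#' @param path Manifest CSV path.
#' @return A data.frame with the five canonical columns; `wav_path` is
#'   resolved against the manifest directory.
#' @export
read_manifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "location", "wav_path", "murmur_label", "outcome_label")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop("manifest is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  base <- dirname(normalizePath(path))
  abs <- file.path(base, df$wav_path)
  df$wav_path <- ifelse(file.exists(df$wav_path), df$wav_path, abs)
  df[, need]
}

#' Write a cohort manifest
#' @param manifest Data.frame with the canonical manifest columns.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}
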