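#' Forward DFT with 1/N normalization
#'
#' Discrete Fourier transform of a signal with the forward 1/N convention:
#' `Z[k] = (1/N) * sum_n z[n] exp(-i 2 pi k n / N)`, k = 0..N-1. Under this
#' convention `Z[0]` is the signal mean. This is the spectrum the discrete
#' Stockwell transform is built from.
#'
#' @param signal A [pcg_signal()].
#' @return Complex vector of length `n_samples` (voice index `n` maps to
#'   frequency `n * fs / N` Hz).
#' @seealso [st_voice()], [stockwell()]
#' @export
st_dft <- function(signal) {
  assert_signal(signal)
  stats::fft(signal$samples) / signal$n_samples
}

#' One voice of the discrete Stockwell transform
#'
#' Computes the Stockwell voice at frequency index `n` (frequency
#' `n * fs / N` Hz): the spectrum is circularly shifted by `n`, multiplied by
#' the frequency-dependent Gaussian `exp(-2 pi^2 k^2 / n^2)`, and carried
#' back to the time domain with the inverse-DFT kernel `exp(+i 2 pi k m / N)`
#' (no 1/N factor — the forward DFT already carries it). The Gaussian's width
#' grows with `n`: the analysis window narrows in time as frequency rises.
#'
#' @param signal A [pcg_signal()].
#' @param n Voice index, `1 <= n <= N-1`. The degenerate `n = 0` voice is
#'   provided by [st_dc_voice()].
#' @param Z Optional precomputed [st_dft()] spectrum (avoids recomputation
#'   when looping over voices).
#' @return Complex vector of length `N`: the voice sampled at every signal
#'   time `m / fs`.
#' @export
st_voice <- function(signal, n, Z = NULL) {
  assert_signal(signal)
  N <- signal$n_samples
  if (length(n) != 1L || n != as.integer(n) || n < 1L || n > N - 1L) {
    stop("voice index 'n' must be an integer in 1..N-1 (N = ", N, ")")
  }
  if (is.null(Z)) Z <- st_dft(signal)
  k <- 0:(N - 1L)
  shifted <- Z[((k + n) %% N) + 1L]
  gauss <- exp(-2 * pi^2 * k^2 / n^2)
  stats::fft(shifted * gauss, inverse = TRUE)
}

#' The zero-frequency (DC) Stockwell voice
#'
#' The Gaussian window is degenerate at frequency zero; by the standard
#' S-transform convention the DC voice is the constant series equal to the
#' signal mean.
#'
#' @param signal A [pcg_signal()].
#' @return Complex vector of length `N`, every element `mean(samples) + 0i`.
#' @export
st_dc_voice <- function(signal) {
  assert_signal(signal)
  rep(complex(real = mean(signal$samples)), signal$n_samples)
}

#' Discrete Stockwell transform over a frequency band
#'
#' Computes [st_voice()] for every voice index whose frequency
#' `n * fs / N` falls inside `band` (inclusive), optionally decimated in
#' frequency (`voice_step`) and time (`time_step`), and stacks the voices
#' into a time-frequency map (TFM). The default band of 20-350 Hz covers the
#' range where heart sounds and most murmurs carry their energy.
#'
#' Decimation exists because the full map can be very large (a 12.5 s signal
#' at 1000 Hz has 4126 voices of 12500 samples in the default band); when
#' the map is destined for a fixed-size image, computing every voice and
#' every time sample is wasted work.
#'
#' @param signal A [pcg_signal()].
#' @param band Numeric length-2, `(f_lo, f_hi)` in Hz with
#'   `0 < f_lo < f_hi <= fs/2`.
#' @param voice_step Keep every `voice_step`-th voice index (default 1).
#' @param time_step Keep every `time_step`-th time sample (default 1).
#' @return A `pcg_tfm`: list with complex matrix `values`
#'   (voices x times), `freqs_hz`, `times_s`, `band`, `fs`, `n_samples`.
#' @examples
#' s <- pcg_signal(sin(2 * pi * 50 * (0:499) / 1000), fs = 1000)
#' tfm <- stockwell(s, band = c(20, 200), voice_step = 2)
#' dim(tfm$values)
#' @export
stockwell <- function(signal, band = c(20, 350), voice_step = 1L,
                      time_step = 1L) {
  assert_signal(signal)
  N <- signal$n_samples
  fs <- signal$fs
  if (length(band) != 2L || !all(is.finite(band))) {
    stop("'band' must be (f_lo, f_hi) in Hz")
  }
  if (band[1] <= 0 || band[1] >= band[2] || band[2] > fs / 2 + 1e-9) {
    stop(
      "invalid band (", band[1], ", ", band[2],
      ") Hz: need 0 < f_lo < f_hi <= fs/2 = ", fs / 2
    )
  }
  voice_step <- as.integer(voice_step)
  time_step <- as.integer(time_step)
  if (voice_step < 1L || time_step < 1L) {
    stop("'voice_step' and 'time_step' must be >= 1")
  }
  # voice n has frequency n*fs/N; inclusive bounds with fp guard
  n_lo <- max(1L, as.integer(ceiling(band[1] * N / fs - 1e-9)))
  n_hi <- as.integer(floor(band[2] * N / fs + 1e-9))
  if (n_hi > N - 1L) n_hi <- N - 1L
  if (n_lo > n_hi) {
    stop(
      "band (", band[1], ", ", band[2], ") Hz contains no voice for N = ",
      N, ", fs = ", fs
    )
  }
  voices <- seq.int(n_lo, n_hi, by = voice_step)
  m_keep <- seq.int(1L, N, by = time_step)

  Z <- st_dft(signal)
  k <- 0:(N - 1L)
  # when time_step divides N the decimated voice equals the short
  # inverse DFT of the aliased (folded) windowed spectrum — exact identity
  fold <- time_step > 1L && N %% time_step == 0L
  Nf <- if (fold) N %/% time_step else N
  Zx <- c(Z, Z) # unwrapped circular access to the shifted spectrum
  vals <- matrix(0i, nrow = length(voices), ncol = length(m_keep))
  for (i in seq_along(voices)) {
    n <- voices[i]
    # the Gaussian underflows below double precision beyond ~1.42 n;
    # restrict the windowed spectrum to its support
    kmax <- min(N - 1L, as.integer(ceiling(1.42 * n)))
    kk <- 0:kmax
    win <- Zx[n + kk + 1L] * exp(-2 * pi^2 * kk^2 / n^2)
    npad <- Nf * ((kmax %/% Nf) + 1L)
    folded <- rowSums(matrix(c(win, rep(0i, npad - kmax - 1L)), nrow = Nf))
    v <- stats::fft(folded, inverse = TRUE)
    vals[i, ] <- if (fold) v else v[m_keep]
  }
  structure(
    list(
      values = vals,
      freqs_hz = voices * fs / N,
      times_s = (m_keep - 1L) / fs,
      band = as.double(band),
      fs = fs,
      n_samples = N
    ),
    class = "pcg_tfm"
  )
}

#' @export
print.pcg_tfm <- function(x, ...) {
  cat(sprintf(
    "<pcg_tfm> %d voices x %d times, %.2f-%.2f Hz, %.3f s\n",
    nrow(x$values), ncol(x$values),
    min(x$freqs_hz), max(x$freqs_hz), max(x$times_s)
  ))
  invisible(x)
}

#' Amplitude of a Stockwell time-frequency map
#'
#' Elementwise modulus `sqrt(Re^2 + Im^2)` of the complex TFM; the
#' nonnegative amplitude map is the basis for image conversion and feature
#' extraction.
#'
#' @param tfm A `pcg_tfm` from [stockwell()].
#' @return A `pcg_amp_tfm` with the same axes and a nonnegative real
#'   `values` matrix.
#' @export
st_amplitude <- function(tfm) {
  if (!inherits(tfm, "pcg_tfm")) stop("expected a 'pcg_tfm' object")
  out <- tfm
  out$values <- Mod(tfm$values)
  class(out) <- c("pcg_amp_tfm", "pcg_tfm")
  out
}

#' Export an amplitude TFM as a grayscale PNG
#'
#' Min-max scales the amplitude map to \[0, 1\] and writes a grayscale PNG
#' with low frequencies at the bottom row, for visual inspection.
#'
#' @param amp A `pcg_amp_tfm` from [st_amplitude()].
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_tfm_png <- function(amp, path) {
  if (!inherits(amp, "pcg_amp_tfm")) stop("expected a 'pcg_amp_tfm' object")
  v <- amp$values
  rng <- range(v)
  img <- if (rng[2] > rng[1]) (v - rng[1]) / (rng[2] - rng[1]) else v * 0
  # row 1 of the matrix is the lowest voice; PNG row 1 is the top
  png::writePNG(img[rev(seq_len(nrow(img))), , drop = FALSE], target = path)
  invisible(path)
}
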