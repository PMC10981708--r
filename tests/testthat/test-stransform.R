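test_that("forward DFT uses the 1/N normalization", {
  # constant signal: DC-only spectrum equal to the constant
  s <- pcg_signal(rep(3.5, 8), fs = 10)
  Z <- st_dft(s)
  expect_equal(Z[1], 3.5 + 0i)
  expect_equal(max(Mod(Z[-1])), 0)

  # unit impulse: flat spectrum at 1/N
  Z <- st_dft(pcg_signal(c(1, 0, 0, 0), fs = 4))
  expect_equal(Z, rep(0.25 + 0i, 4))

  # alternating signal: all energy at Nyquist
  Z <- st_dft(pcg_signal(c(1, -1, 1, -1), fs = 4))
  expect_equal(Z[3], 1 + 0i)
  expect_equal(max(Mod(Z[-3])), 0)
})

test_that("FFT-based voices match the direct double-sum evaluation", {
  for (N in c(16, 64)) {
    s <- random_signal(N, seed = N)
    Z <- st_dft(s)
    for (n in 1:(N - 1)) {
      expect_lt(max(Mod(st_voice(s, n, Z) - direct_voice(s, n))), 1e-9)
    }
  }
})

test_that("impulse voice has flat amplitude 1/N", {
  s <- pcg_signal(c(1, 0, 0, 0), fs = 4)
  expect_equal(Mod(st_voice(s, 1)), rep(0.25, 4), tolerance = 1e-6)
})

test_that("time-averaging a voice collapses to the DFT coefficient", {
  set.seed(42)
  for (rep in 1:5) {
    N <- sample(c(16, 32, 64), 1)
    s <- random_signal(N)
    Z <- st_dft(s)
    for (n in sample(1:(N - 1), 5)) {
      expect_lt(Mod(mean(st_voice(s, n, Z)) - Z[n + 1]), 1e-10)
    }
  }
})

test_that("a pure sinusoid localizes at its own voice", {
  # real signals have a conjugate spectral peak at N - n0, so localization
  # is over the physical voices n <= N/2 (any valid band ends at fs/2)
  N <- 64
  fs <- 64
  for (n0 in c(5, 12, 25)) {
    s <- make_sine(n0 * fs / N, fs, N)
    Z <- st_dft(s)
    mean_amp <- vapply(
      1:(N / 2),
      function(n) mean(Mod(st_voice(s, n, Z))),
      numeric(1)
    )
    expect_equal(which.max(mean_amp), n0)
  }
})

test_that("the Gaussian window widens in frequency as the voice rises", {
  k <- 3
  g <- exp(-2 * pi^2 * k^2 / (1:50)^2)
  expect_true(all(diff(g) > 0))
})

test_that("DC voice is the signal mean everywhere", {
  expect_equal(
    st_dc_voice(pcg_signal(c(1, 2, 3, 4), 4)),
    rep(2.5 + 0i, 4)
  )
  expect_equal(
    st_dc_voice(pcg_signal(c(1, -1, 1, -1), 4)),
    rep(0 + 0i, 4)
  )
})

test_that("stockwell() stacks the per-voice transforms with correct axes", {
  s <- random_signal(100, fs = 100, seed = 3)
  tfm <- stockwell(s, band = c(10, 30))
  expect_s3_class(tfm, "pcg_tfm")
  expect_equal(tfm$freqs_hz, 10:30)
  expect_equal(ncol(tfm$values), 100)
  Z <- st_dft(s)
  for (i in c(1, 7, 21)) {
    n <- round(tfm$freqs_hz[i] * 100 / 100)
    expect_equal(tfm$values[i, ], st_voice(s, n, Z), tolerance = 1e-12)
  }

  # single-voice band
  one <- stockwell(s, band = c(9.9, 10.1))
  expect_equal(nrow(one$values), 1L)

  # empty band errors
  expect_error(stockwell(s, band = c(10.2, 10.8)), "no voice")
  expect_error(stockwell(s, band = c(-5, 10)), "invalid band")
  expect_error(stockwell(s, band = c(40, 60)), "invalid band")
})

test_that("the default band on a 12.5 s, 1000 Hz record spans 20-350 Hz", {
  s <- random_signal(12500, fs = 1000, seed = 4)
  tfm <- stockwell(s, band = c(20, 350), voice_step = 1, time_step = 2500)
  expect_equal(nrow(tfm$values), 4126L)
  expect_equal(tfm$freqs_hz[1], 20)
  expect_equal(tfm$freqs_hz[4126], 350)
})

test_that("time decimation by a divisor of N is exact", {
  s <- random_signal(120, fs = 60, seed = 9)
  full <- stockwell(s, band = c(5, 25))
  dec <- stockwell(s, band = c(5, 25), time_step = 4)
  expect_equal(dec$values, full$values[, seq(1, 120, by = 4)],
               tolerance = 1e-12)
  expect_equal(dec$times_s, full$times_s[seq(1, 120, by = 4)])
})

test_that("the transform is linear in the signal", {
  N <- 64
  x <- random_signal(N, seed = 11)
  y <- random_signal(N, seed = 12)
  mix <- pcg_signal(2 * x$samples - 3 * y$samples, fs = x$fs)
  tx <- stockwell(x, band = c(5, 20))
  ty <- stockwell(y, band = c(5, 20))
  tm <- stockwell(mix, band = c(5, 20))
  expect_equal(tm$values, 2 * tx$values - 3 * ty$values, tolerance = 1e-10)
})

test_that("amplitude is the elementwise modulus", {
  s <- random_signal(32, seed = 5)
  tfm <- stockwell(s, band = c(5, 10))
  tfm$values[1, 1] <- 3 + 4i
  amp <- st_amplitude(tfm)
  expect_equal(amp$values[1, 1], 5)
  expect_true(all(amp$values >= 0))
  expect_equal(dim(amp$values), dim(tfm$values))

  # invariant to a global phase rotation
  rot <- tfm
  rot$values <- tfm$values * exp(0.7i)
  expect_equal(st_amplitude(rot)$values, st_amplitude(tfm)$values,
               tolerance = 1e-12)
})

test_that("invalid signals are rejected", {
  expect_error(pcg_signal(numeric(0), 10), "at least 2")
  expect_error(pcg_signal(c(1, NA), 10), "finite")
  expect_error(pcg_signal(c(1, 2), -1), "positive")
  s <- pcg_signal(c(1, 2, 3, 4), 4)
  expect_error(st_voice(s, 0), "1..N-1")
  expect_error(st_voice(s, 4), "1..N-1")
})

test_that("TFM exports to a grayscale PNG", {
  s <- make_sine(10, 64, 64)
  amp <- st_amplitude(stockwell(s, band = c(5, 20)))
  path <- tempfile(fileext = ".png")
  write_tfm_png(amp, path)
  img <- png::readPNG(path)
  expect_equal(dim(img), dim(amp$values))
  expect_true(all(img >= 0 & img <= 1))
})
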