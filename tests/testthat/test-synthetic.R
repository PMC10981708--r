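energy_fraction_above <- function(s, f0) {
  spec <- Mod(stats::fft(s$samples))^2
  freqs <- (seq_along(spec) - 1) * s$fs / length(spec)
  half <- freqs <= s$fs / 2
  sum(spec[half & freqs > f0]) / sum(spec[half])
}

band_energy <- function(s, band) {
  spec <- Mod(stats::fft(s$samples))^2
  freqs <- (seq_along(spec) - 1) * s$fs / length(spec)
  sum(spec[freqs >= band[1] & freqs <= band[2]])
}

test_that("murmur-free recordings keep their energy below 100 Hz", {
  cfg <- sim_config()
  for (seed in 1:5) {
    s <- simulate_recording(cfg, murmur = FALSE, location = "PV",
                            duration_s = 10, seed = seed)
    expect_lt(energy_fraction_above(s, 100), 0.10)
  }
})

test_that("a murmur adds energy in the murmur band, scaled by location gain", {
  cfg <- sim_config()
  for (seed in 1:3) {
    clean <- simulate_recording(cfg, murmur = FALSE, location = "PV",
                                duration_s = 10, seed = seed)
    mur <- simulate_recording(cfg, murmur = TRUE, location = "PV",
                              duration_s = 10, seed = seed)
    expect_gt(band_energy(mur, c(100, 300)), band_energy(clean, c(100, 300)))
  }
})

test_that("S1 onsets are spaced by the cardiac period", {
  cfg <- sim_config()
  s <- simulate_recording(cfg, murmur = FALSE, heart_rate_bpm = 120,
                          duration_s = 5, seed = 2)
  # the envelope's autocovariance peaks at the beat-to-beat lag
  env <- abs(s$samples)
  ac <- stats::acf(env, lag.max = 3000, plot = FALSE)$acf[-1]
  search <- 1200:2800 # plausible period range in samples
  lag <- search[which.max(ac[search])]
  expect_lt(abs(lag - 0.5 * s$fs), 1.5) # 0.5 s at 120 bpm, within a sample
})

test_that("degraded recordings are dominated by broadband noise", {
  cfg <- sim_config()
  clean <- simulate_recording(cfg, murmur = FALSE, duration_s = 8, seed = 3)
  degr <- simulate_recording(cfg, murmur = FALSE, duration_s = 8, seed = 3,
                             degraded = TRUE)
  expect_gt(energy_fraction_above(degr, 350), 5 * energy_fraction_above(clean, 350))
})

test_that("cohort label sampling is seeded and respects the fractions", {
  coh <- simulate_cohort(100, murmur_prevalence = 0.3, unknown_frac = 0.1,
                         config = quick_sim_config(), seed = 21)
  labs <- vapply(coh$patients, `[[`, "", "murmur_label")
  expect_equal(length(labs), 100)
  n_present <- sum(labs == "Present")
  expect_true(abs(n_present - 30) < 15) # binomial sampling around 0.3
  coh2 <- simulate_cohort(100, murmur_prevalence = 0.3, unknown_frac = 0.1,
                          config = quick_sim_config(), seed = 21)
  labs2 <- vapply(coh2$patients, `[[`, "", "murmur_label")
  expect_identical(labs, labs2)

  none <- simulate_cohort(30, unknown_frac = 0,
                          config = quick_sim_config(), seed = 5)
  expect_false("Unknown" %in% vapply(none$patients, `[[`, "", "murmur_label"))
})

test_that("some patients drop locations but all keep at least two", {
  coh <- simulate_cohort(60, config = quick_sim_config(), seed = 8)
  n_locs <- vapply(coh$patients, function(p) length(p$recordings), 1L)
  expect_true(any(n_locs < 4))
  expect_true(all(n_locs >= 2))
  expect_true(all(unlist(lapply(coh$patients, function(p) {
    names(p$recordings) %in% c("AV", "PV", "TV", "MV")
  }))))
})

test_that("an emitted cohort round-trips through the WAV reader bit-exactly", {
  dir <- tempfile()
  coh <- simulate_cohort(4, seed = 9, dir = dir,
                         config = quick_sim_config())
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_true(file.exists(file.path(dir, "cohort.json")))
  loaded <- load_cohort(file.path(dir, "manifest.csv"))
  expect_equal(length(loaded$patients), 4)
  for (i in 1:4) {
    p0 <- coh$patients[[i]]
    p1 <- loaded$patients[[i]]
    expect_identical(names(p0$recordings), names(p1$recordings))
    for (loc in names(p0$recordings)) {
      expect_identical(p1$recordings[[loc]]$samples,
                       p0$recordings[[loc]]$samples)
    }
    expect_identical(p1$murmur_label, p0$murmur_label)
  }
})

test_that("simulator configuration is validated", {
  expect_error(sim_config(murmur_band_hz = c(100, 3000)), "fs/2")
  expect_error(sim_config(duration_range_s = c(-1, 5)), "positive")
  expect_error(simulate_cohort(1), "at least 2")
  expect_error(simulate_cohort(10, murmur_prevalence = 0.8,
                               unknown_frac = 0.4), "sum <= 1")
  expect_error(simulate_recording(sim_config(), location = "XX"), "location")
})
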