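#' Synthetic PCG simulation configuration
#'
#' Parameters for the heart-sound simulator. Defaults mirror a pediatric
#' screening cohort: recordings of 5-65 s at 4000 Hz, heart rates of
#' 70-140 bpm, systolic murmurs as band-limited (100-300 Hz) noise whose
#' gain varies across the four auscultation locations, and a broadband
#' sensor noise floor 30 dB below the S1 peak.
#'
#' @param fs Sampling rate in Hz (default 4000).
#' @param duration_range_s Range recordings' durations are drawn from
#'   uniformly (default `c(5, 65)`).
#' @param heart_rate_range_bpm Heart-rate range per patient (default
#'   `c(70, 140)`).
#' @param murmur_band_hz Murmur noise band (default `c(100, 300)`).
#' @param murmur_snr_db Murmur level above the noise floor in dB
#'   (default 26).
#' @param location_gain Named per-location murmur gain multipliers.
#' @param noise_floor_db Broadband noise level relative to the unit S1 peak
#'   in dB (default -30).
#' @param degraded_noise_db Noise level used for quality-degraded
#'   ("Unknown") recordings (default -8), nearly drowning the heart sounds.
#' @return A `pcg_sim_config` list.
#' @export
sim_config <- function(fs = 4000, duration_range_s = c(5, 65),
                       heart_rate_range_bpm = c(70, 140),
                       murmur_band_hz = c(100, 300), murmur_snr_db = 26,
                       location_gain = c(AV = 0.6, PV = 1.0, TV = 0.7, MV = 0.9),
                       noise_floor_db = -30, degraded_noise_db = -8) {
  if (murmur_band_hz[1] <= 0 || murmur_band_hz[2] >= fs / 2 ||
        murmur_band_hz[1] >= murmur_band_hz[2]) {
    stop("'murmur_band_hz' must lie strictly inside (0, fs/2)")
  }
  if (any(duration_range_s <= 0)) stop("durations must be positive")
  if (any(location_gain < 0)) stop("location gains must be >= 0")
  if (!all(LOCATIONS %in% names(location_gain))) {
    stop("'location_gain' must name all of ", paste(LOCATIONS, collapse = ", "))
  }
  structure(
    list(
      fs = fs, duration_range_s = duration_range_s,
      heart_rate_range_bpm = heart_rate_range_bpm,
      murmur_band_hz = murmur_band_hz, murmur_snr_db = murmur_snr_db,
      location_gain = location_gain, noise_floor_db = noise_floor_db,
      degraded_noise_db = degraded_noise_db
    ),
    class = "pcg_sim_config"
  )
}

# Periodic train of Gaussian-enveloped tone bursts, one per cardiac cycle,
# centred at phase `t0` within the cycle. Vectorized over the whole signal:
# d is the signed time distance to the nearest burst centre.
burst_train <- function(t, cycle, t0, freq, amp, dur) {
  d <- ((t - t0 + cycle / 2) %% cycle) - cycle / 2
  amp * exp(-0.5 * (d / (dur / 3))^2) * sin(2 * pi * freq * d)
}

# Band-limited Gaussian noise: white noise restricted to `band` by
# brick-wall masking in the frequency domain. Work at a 2-3-5-smooth padded
# length (mixed-radix FFTs are O(n^2) at awkward lengths) and truncate.
bandpass_noise <- function(n, fs, band) {
  np <- stats::nextn(n, c(2L, 3L, 5L))
  z <- stats::fft(stats::rnorm(np))
  fr <- (seq_len(np) - 1L) * fs / np
  fr <- pmin(fr, fs - fr) # two-sided spectrum folds at Nyquist
  z[fr < band[1] | fr > band[2]] <- 0i
  (Re(stats::fft(z, inverse = TRUE)) / np)[seq_len(n)]
}

#' Simulate one PCG recording
#'
#' Generates a periodic train of S1 and S2 heart sounds — short
#' Gaussian-enveloped tone bursts with centre frequencies near 35 Hz (S1)
#' and 60 Hz (S2), the S2 burst placed 30% of the cardiac cycle after S1 —
#' plus broadband sensor noise. A murmur, when present, is band-limited
#' noise in `murmur_band_hz`, gated to the systolic interval by a raised-
#' cosine window and scaled by the location's gain and `murmur_snr_db`.
#' Abnormal-outcome patients get a louder, higher-pitched S2. Deterministic
#' given `seed`.
#'
#' @param config A [sim_config()].
#' @param murmur Logical: inject a systolic murmur.
#' @param location Auscultation location tag (AV/PV/TV/MV), selects the
#'   murmur gain.
#' @param heart_rate_bpm Heart rate; drawn from the config range if `NULL`.
#' @param duration_s Duration; drawn from the config range if `NULL`.
#' @param degraded Logical: simulate a low-quality recording (noise floor
#'   raised to `degraded_noise_db`).
#' @param abnormal Logical: apply the abnormal-outcome S2 signature.
#' @param seed Integer seed.
#' @return A [pcg_signal()] at `config$fs`, peak-normalized to 0.9 and
#'   quantized to the 16-bit grid so WAV round-trips are exact.
#' @export
simulate_recording <- function(config = sim_config(), murmur = FALSE,
                               location = "AV", heart_rate_bpm = NULL,
                               duration_s = NULL, degraded = FALSE,
                               abnormal = FALSE, seed = 1L) {
  if (!inherits(config, "pcg_sim_config")) {
    stop("'config' must come from sim_config()")
  }
  if (!location %in% LOCATIONS) stop("unknown location: ", location)
  with_local_seed(seed, {
    fs <- config$fs
    if (is.null(duration_s)) {
      duration_s <- stats::runif(1, config$duration_range_s[1],
                                 config$duration_range_s[2])
    }
    if (is.null(heart_rate_bpm)) {
      heart_rate_bpm <- stats::runif(1, config$heart_rate_range_bpm[1],
                                     config$heart_rate_range_bpm[2])
    }
    n <- as.integer(round(duration_s * fs))
    cycle <- 60 / heart_rate_bpm
    s1_times <- seq(0.1, n / fs, by = cycle)
    s2_offset <- 0.3 * cycle

    s1_freq <- stats::runif(1, 30, 45)
    s2_freq <- stats::runif(1, 50, 70)
    s2_amp <- 0.8
    if (abnormal) {
      s2_freq <- s2_freq + 15
      s2_amp <- 1.1
    }
    tgrid <- (seq_len(n) - 1L) / fs
    x <- burst_train(tgrid, cycle, s1_times[1], s1_freq, 1.0, 0.045) +
      burst_train(tgrid, cycle, s1_times[1] + s2_offset, s2_freq, s2_amp,
                  0.035)

    noise_db <- if (degraded) config$degraded_noise_db else config$noise_floor_db
    x <- x + 10^(noise_db / 20) * stats::rnorm(n)

    if (murmur) {
      gain <- config$location_gain[[location]]
      amp <- gain * 10^((config$noise_floor_db + config$murmur_snr_db) / 20)
      mur <- bandpass_noise(n, fs, config$murmur_band_hz)
      mur <- mur / stats::sd(mur)
      # raised-cosine gate over each systolic interval (S1 -> S2),
      # computed from the cardiac phase in one vectorized pass
      t <- (seq_len(n) - 1L) / fs
      phase <- (t - s1_times[1]) %% cycle
      a <- 0.02
      b <- s2_offset - 0.01
      gate <- ifelse(phase >= a & phase <= b,
        0.5 * (1 - cos(2 * pi * (phase - a) / (b - a))), 0
      )
      x <- x + amp * gate * mur
    }
    x <- 0.9 * x / max(abs(x))
    x <- round(x * 32767) / 32767 # 16-bit grid: WAV round-trip is exact
    out <- pcg_signal(x, fs = fs)
  })
  out
}

#' Simulate a labeled synthetic PCG cohort
#'
#' Samples per-patient labels (murmur Present with probability
#' `murmur_prevalence`, Unknown with probability `unknown_frac`, otherwise
#' Absent; outcome Abnormal with probability `abnormal_prevalence`,
#' independently) and generates recordings at every retained auscultation
#' location. Present patients get the murmur at all of their locations,
#' scaled by the per-location gain profile; Unknown patients get
#' quality-degraded recordings; a random ~30% of patients drop 1-2
#' locations to exercise missing-location handling. Abnormal patients carry
#' the abnormal S2 signature. Deterministic given `seed`.
#'
#' @param n_patients Number of patients (>= 2).
#' @param murmur_prevalence Probability of murmur Present (default 0.3).
#' @param unknown_frac Probability of the Unknown (low-quality) label
#'   (default 0.1). `murmur_prevalence + unknown_frac` must be <= 1.
#' @param abnormal_prevalence Probability of Abnormal outcome (default 0.5).
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @param dir Output directory; when non-`NULL`, WAV files, a manifest CSV
#'   (`manifest.csv`) and a JSON parameter sidecar (`cohort.json`) are
#'   written in the canonical layout (`<patient>_<LOC>.wav`).
#' @return A `pcg_cohort`: list with `patients` (each with `patient_id`,
#'   `recordings` keyed by location, `murmur_label`, `outcome_label`) and
#'   `manifest` (data.frame; `wav_path` populated when `dir` is given).
#' @export
simulate_cohort <- function(n_patients, murmur_prevalence = 0.3,
                            unknown_frac = 0.1, abnormal_prevalence = 0.5,
                            config = sim_config(), seed = 1L, dir = NULL) {
  if (n_patients < 2L) stop("need at least 2 patients")
  if (murmur_prevalence < 0 || unknown_frac < 0 ||
        murmur_prevalence + unknown_frac > 1) {
    stop("need murmur_prevalence, unknown_frac >= 0 with sum <= 1")
  }
  if (abnormal_prevalence < 0 || abnormal_prevalence > 1) {
    stop("'abnormal_prevalence' must be in [0, 1]")
  }
  with_local_seed(seed, {
    u <- stats::runif(n_patients)
    murmur_label <- ifelse(u < murmur_prevalence, "Present",
      ifelse(u < murmur_prevalence + unknown_frac, "Unknown", "Absent")
    )
    outcome_label <- ifelse(stats::runif(n_patients) < abnormal_prevalence,
      "Abnormal", "Normal"
    )
    rec_seeds <- sample.int(.Machine$integer.max - 1L, n_patients * 4L)
    patients <- vector("list", n_patients)
    for (i in seq_len(n_patients)) {
      pid <- sprintf("SP%04d", i)
      locs <- LOCATIONS
      if (stats::runif(1) < 0.3) {
        locs <- setdiff(locs, sample(LOCATIONS, sample(1:2, 1)))
      }
      hr <- stats::runif(1, config$heart_rate_range_bpm[1],
                         config$heart_rate_range_bpm[2])
      recs <- list()
      for (j in seq_along(locs)) {
        loc <- locs[j]
        recs[[loc]] <- simulate_recording(
          config,
          murmur = murmur_label[i] == "Present",
          location = loc, heart_rate_bpm = hr,
          degraded = murmur_label[i] == "Unknown",
          abnormal = outcome_label[i] == "Abnormal",
          seed = rec_seeds[(i - 1L) * 4L + j]
        )
      }
      patients[[i]] <- list(
        patient_id = pid, recordings = recs,
        murmur_label = murmur_label[i], outcome_label = outcome_label[i]
      )
    }
  })
  rows <- do.call(rbind, lapply(patients, function(p) {
    data.frame(
      patient_id = p$patient_id, location = names(p$recordings),
      wav_path = sprintf("%s_%s.wav", p$patient_id, names(p$recordings)),
      murmur_label = p$murmur_label, outcome_label = p$outcome_label,
      stringsAsFactors = FALSE
    )
  }))
  rownames(rows) <- NULL
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (p in patients) {
      for (loc in names(p$recordings)) {
        write_wav(
          p$recordings[[loc]],
          file.path(dir, sprintf("%s_%s.wav", p$patient_id, loc))
        )
      }
    }
    write_manifest(rows, file.path(dir, "manifest.csv"))
    jsonlite::write_json(
      list(
        n_patients = n_patients, murmur_prevalence = murmur_prevalence,
        unknown_frac = unknown_frac,
        abnormal_prevalence = abnormal_prevalence, seed = seed,
        config = unclass(config)
      ),
      file.path(dir, "cohort.json"),
      auto_unbox = TRUE, digits = NA
    )
  }
  structure(list(patients = patients, manifest = rows), class = "pcg_cohort")
}

#' @export
print.pcg_cohort <- function(x, ...) {
  lab <- table(vapply(x$patients, `[[`, "", "murmur_label"))
  cat(sprintf(
    "<pcg_cohort> %d patients, %d recordings (murmur: %s)\n",
    length(x$patients), nrow(x$manifest),
    paste(names(lab), as.integer(lab), sep = "=", collapse = ", ")
  ))
  invisible(x)
}

#' Load a cohort from a manifest into memory
#'
#' Reads every WAV referenced by a manifest (as written by
#' [simulate_cohort()] or assembled by hand over a CirCor-style dataset)
#' into a `pcg_cohort`.
#'
#' @param manifest A manifest data.frame or a path to a manifest CSV.
#' @return A `pcg_cohort`.
#' @export
load_cohort <- function(manifest) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  ids <- unique(manifest$patient_id)
  patients <- lapply(ids, function(pid) {
    sub <- manifest[manifest$patient_id == pid, , drop = FALSE]
    recs <- list()
    for (r in seq_len(nrow(sub))) {
      recs[[sub$location[r]]] <- read_wav(sub$wav_path[r])
    }
    list(
      patient_id = pid, recordings = recs,
      murmur_label = sub$murmur_label[1], outcome_label = sub$outcome_label[1]
    )
  })
  structure(list(patients = patients, manifest = manifest),
            class = "pcg_cohort")
}
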