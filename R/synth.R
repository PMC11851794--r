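#' Synthetic multi-subject EEG cohorts
#'
#' Generates 19-channel resting-state-like EEG: per channel, a sum of
#' band-limited oscillations (random-phase sinusoids with slowly waxing and
#' waning amplitude envelopes and a center frequency drawn uniformly within
#' the band) on top of 1/f-shaped background noise and a white noise floor,
#' with optional high-amplitude biphasic spike artifacts.  Group effects are
#' multiplicative band-amplitude factors on selected channels (defaults
#' echo resting-state depression findings: elevated frontal theta and
#' reduced left-frontal alpha in the patient group), and per-subject gain is
#' log-normal.  With all effect multipliers at 1 the group label carries no
#' signal (a null cohort).
#'
#' @name synthetic-eeg
NULL

FRONTAL_CHANNELS <- c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8")

#' One multiplicative group effect
#'
#' @param band band name (must appear in the cohort's band table).
#' @param channels channel names the effect applies to.
#' @param multiplier amplitude factor applied to the patient group (> 0).
#' @export
group_effect <- function(band, channels, multiplier) {
  stopifnot(multiplier > 0)
  list(band = band, channels = channels, multiplier = multiplier)
}

#' Cohort specification
#'
#' Defaults emulate the target cohort: 30 patients, 28 controls, 5-minute
#' recordings at 256 Hz, with resting-EEG-like band amplitudes (strong
#' alpha/delta, moderate theta, weak beta/gamma, in microvolts of
#' oscillation amplitude).
#'
#' @param n_mdd,n_hc subjects per group.
#' @param duration_s recording length in seconds (>= 5).
#' @param sampling_rate_hz sampling rate.
#' @param band_amplitudes named vector of mean oscillation amplitudes (uV)
#'   for the bands of [default_bands()].
#' @param effects list of [group_effect()]s applied to the patient group;
#'   `list()` gives a null cohort.
#' @param subject_sd sd of the log-normal per-subject gain.
#' @param pink_sd,pink_exponent 1/f background noise scale (uV) and
#'   exponent.
#' @param white_sd white noise floor (uV).
#' @param artifact_rate_per_min expected biphasic spike artifacts per
#'   minute (0 disables).
#' @param artifact_amp_uv spike amplitude range (uV), beyond the +/-100 uV
#'   rejection threshold by default.
#' @param seed master seed; per-subject seeds are derived from it.
#' @export
cohort_spec <- function(n_mdd = 30L, n_hc = 28L, duration_s = 300,
                        sampling_rate_hz = 256,
                        band_amplitudes = c(delta = 9, theta = 5,
                                            alpha = 9, beta = 3,
                                            gamma = 1.5),
                        effects = list(
                          group_effect("theta", FRONTAL_CHANNELS, 1.5),
                          group_effect("alpha", c("F3", "F7"), 0.8)),
                        subject_sd = 0.2, pink_sd = 3, pink_exponent = 1,
                        white_sd = 1.5, artifact_rate_per_min = 0,
                        artifact_amp_uv = c(150, 300), seed = 1L) {
  stopifnot(duration_s >= 5, all(band_amplitudes >= 0), subject_sd >= 0,
            pink_sd >= 0, white_sd >= 0, artifact_rate_per_min >= 0)
  for (ef in effects) stopifnot(ef$multiplier > 0)
  structure(list(n_mdd = as.integer(n_mdd), n_hc = as.integer(n_hc),
                 duration_s = duration_s,
                 sampling_rate_hz = sampling_rate_hz,
                 band_amplitudes = band_amplitudes, effects = effects,
                 subject_sd = subject_sd, pink_sd = pink_sd,
                 pink_exponent = pink_exponent, white_sd = white_sd,
                 artifact_rate_per_min = artifact_rate_per_min,
                 artifact_amp_uv = artifact_amp_uv, seed = as.integer(seed)),
            class = "cohort_spec")
}

# 1/f^a noise via FFT shaping, scaled to unit sd
pink_noise <- function(n, exponent) {
  nf <- nextn(n, 2L)
  half <- nf %/% 2L
  f <- seq_len(half)                         # positive-frequency bins
  mag <- f^(-exponent / 2)
  phase <- stats::runif(half, 0, 2 * pi)
  spec <- complex(modulus = mag, argument = phase)
  full <- c(0, spec[-half], Re(spec[half]),
            Conj(rev(spec[-half])))
  x <- Re(stats::fft(full, inverse = TRUE))[seq_len(n)]
  x / stats::sd(x)
}

# slow positive amplitude envelope, mean ~1 (low-pass < cutoff Hz)
slow_envelope <- function(n, sampling_rate_hz, cutoff_hz = 0.5,
                          depth = 0.5) {
  nf <- nextn(n, 2L)
  z <- stats::rnorm(nf)
  zf <- stats::fft(z)
  freqs <- c(seq(0, nf / 2), seq(-nf / 2 + 1, -1)) * sampling_rate_hz / nf
  zf[abs(freqs) > cutoff_hz] <- 0
  env <- Re(stats::fft(zf, inverse = TRUE))[seq_len(n)] / nf
  s <- stats::sd(env)
  if (s < 1e-12) return(rep(1, n))
  # bounded modulation: rhythms wax and wane within [0, 2x] their mean
  pmin(pmax(0, 1 + depth * (env - mean(env)) / s), 2)
}

# band-limited oscillation: an amplitude-modulated sum of random-phase
# sinusoids with frequencies uniform in the band (spectral synthesis of a
# narrowband noise process -- real EEG rhythms wander in frequency rather
# than holding a stable pure tone).  RMS equals amplitude / sqrt(2), i.e.
# the power of a single sinusoid with that amplitude.
band_oscillation <- function(n, sampling_rate_hz, low_hz, high_hz,
                             amplitude, n_components = 12L) {
  # keep the envelope sidebands inside the nominal band
  margin <- min(0.6, (high_hz - low_hz) / 4)
  t <- seq_len(n) / sampling_rate_hz
  f <- stats::runif(n_components, low_hz + margin, high_hz - margin)
  phi <- stats::runif(n_components, 0, 2 * pi)
  x <- sin(outer(t, 2 * pi * f) + rep(phi, each = n)) %*%
    rep(1 / sqrt(n_components), n_components)
  env <- slow_envelope(n, sampling_rate_hz)
  amplitude * env * as.numeric(x)
}

biphasic_spike <- function(width_samples) {
  t <- seq(-3, 3, length.out = width_samples)
  s <- t * exp(-t^2)                       # Gaussian derivative
  s / max(abs(s))
}

#' Generate one synthetic subject recording
#'
#' @param spec a `cohort_spec`.
#' @param group `"mdd"` (label 1; group effects applied) or `"hc"`
#'   (label 0).
#' @param subject_seed RNG seed for this subject; the output is a pure
#'   function of (spec, group, subject_seed).
#' @param subject_id identifier for the recording.
#' @return An `eeg_recording` in microvolts.
#' @export
generate_subject <- function(spec, group = c("hc", "mdd"),
                             subject_seed = 1L, subject_id = NULL) {
  group <- match.arg(group)
  set.seed(subject_seed)
  fs <- spec$sampling_rate_hz
  n <- round(spec$duration_s * fs)
  bands <- default_bands()
  channels <- MONTAGE_CHANNELS
  gain <- exp(stats::rnorm(1, 0, spec$subject_sd))
  data <- matrix(0, length(channels), n,
                 dimnames = list(channels, NULL))
  for (ci in seq_along(channels)) {
    x <- numeric(n)
    for (bi in seq_len(nrow(bands))) {
      amp <- spec$band_amplitudes[[bands$name[bi]]]
      if (group == "mdd") {
        for (ef in spec$effects) {
          if (ef$band == bands$name[bi] && channels[ci] %in% ef$channels)
            amp <- amp * ef$multiplier
        }
      }
      if (amp > 0)
        x <- x + band_oscillation(n, fs, bands$low_hz[bi], bands$high_hz[bi],
                                  amp * gain)
    }
    if (spec$pink_sd > 0)
      x <- x + spec$pink_sd * pink_noise(n, spec$pink_exponent)
    if (spec$white_sd > 0)
      x <- x + stats::rnorm(n, 0, spec$white_sd)
    data[ci, ] <- x
  }
  if (spec$artifact_rate_per_min > 0) {
    n_spikes <- stats::rpois(1, spec$artifact_rate_per_min *
                               spec$duration_s / 60)
    width <- round(0.25 * fs)
    shape <- biphasic_spike(width)
    for (k in seq_len(n_spikes)) {
      at <- sample.int(n - width, 1L)
      amp <- sample(c(-1, 1), 1L) *
        stats::runif(1, spec$artifact_amp_uv[1], spec$artifact_amp_uv[2])
      chs <- sample(seq_along(channels), sample(3:6, 1L))
      for (ci in chs)
        data[ci, at:(at + width - 1L)] <-
          data[ci, at:(at + width - 1L)] + amp * shape
    }
  }
  if (is.null(subject_id))
    subject_id <- paste0(group, formatC(subject_seed %% 1000L, width = 3,
                                        flag = "0"))
  new_recording(data, channels, fs, subject_id,
                label = if (group == "mdd") 1 else 0)
}

#' Generate a full cohort
#'
#' Subject seeds are drawn (reproducibly) from the master seed, so
#' recordings are mutually distinct but the cohort is a pure function of
#' the spec.
#'
#' @param spec a `cohort_spec`.
#' @return List with `recordings` and a `manifest` data.frame (subject_id,
#'   label, seed).
#' @export
generate_cohort <- function(spec) {
  set.seed(spec$seed)
  n <- spec$n_mdd + spec$n_hc
  seeds <- sample.int(.Machine$integer.max - 1L, n)
  groups <- c(rep("mdd", spec$n_mdd), rep("hc", spec$n_hc))
  ids <- c(sprintf("mdd%02d", seq_len(spec$n_mdd)),
           sprintf("hc%02d", seq_len(spec$n_hc)))
  recordings <- lapply(seq_len(n), function(i)
    generate_subject(spec, groups[i], seeds[i], ids[i]))
  manifest <- data.frame(subject_id = ids,
                         label = ifelse(groups == "mdd", 1L, 0L),
                         seed = seeds, stringsAsFactors = FALSE)
  list(recordings = recordings, manifest = manifest)
}
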