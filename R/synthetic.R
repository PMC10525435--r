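#' Configuration for the synthetic respiratory-modulated signal generator
#'
#' The generator emulates the three mechanisms by which respiration imprints
#' on cardiac signals: baseline wander (an additive component at the
#' respiratory frequency), amplitude modulation of the cardiac pulse train,
#' and frequency modulation of the beat rate. On top sit broadband Gaussian
#' noise and a single high-frequency sinusoidal motion-artifact component.
#' The respiratory frequency driving all three mechanisms is known exactly,
#' so every downstream stage can be validated against ground truth.
#'
#' @param n_subjects Number of subjects to simulate.
#' @param duration_s Recording duration in seconds (default 480, i.e. the
#'   8 min of the clinical benchmark recordings).
#' @param fs Signal sampling rate in Hz (default 125).
#' @param hr_range Mean heart-rate interval in beats/min, drawn uniformly per
#'   subject.
#' @param rr_range Mean respiratory-rate interval in breaths/min, drawn
#'   uniformly per subject; must lie inside (6, 36), the physiologically
#'   viable band targeted by the respiratory band-pass.
#' @param rr_drift_sd Standard deviation of the RR random walk per minute
#'   (breaths/min); the walk is reflected at `rr_range`.
#' @param bw_amp Baseline-wander amplitude as a fraction of the cardiac
#'   pulse amplitude.
#' @param am_depth Fractional amplitude-modulation depth.
#' @param fm_depth Fractional beat-frequency modulation depth.
#' @param noise_sd White-noise standard deviation (fraction of pulse amplitude).
#' @param artifact_freq Motion-artifact frequency in Hz.
#' @param artifact_amp Motion-artifact amplitude (fraction of pulse amplitude).
#' @param seed Integer master seed; subject i (0-based) uses `seed + i`.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_subjects = 1, duration_s = 480, fs = 125,
                             hr_range = c(55, 95), rr_range = c(8, 28),
                             rr_drift_sd = 1.0, bw_amp = 0.3, am_depth = 0.2,
                             fm_depth = 0.05, noise_sd = 0.1,
                             artifact_freq = 20, artifact_amp = 0.2,
                             seed = 1L) {
  cfg <- structure(as.list(environment()), class = "synthetic_config")
  if (cfg$n_subjects < 1) transrr_error("transrr_parameter_error", "n_subjects must be >= 1")
  if (cfg$rr_range[1] <= 6 || cfg$rr_range[2] >= 36 || diff(cfg$rr_range) < 0)
    transrr_error("transrr_parameter_error",
                  "rr_range must be an interval inside (6, 36) breaths/min")
  amps <- c(cfg$bw_amp, cfg$am_depth, cfg$fm_depth, cfg$noise_sd, cfg$artifact_amp)
  if (any(amps < 0))
    transrr_error("transrr_parameter_error", "modulation/noise amplitudes must be >= 0")
  if (cfg$duration_s <= 0 || cfg$fs <= 0)
    transrr_error("transrr_parameter_error", "duration_s and fs must be positive")
  cfg
}

# Bounded random walk at 1 Hz reflected at [lo, hi]; per-step sd is the
# per-minute sd scaled by sqrt(1/60).
rr_random_walk <- function(n, start, step_sd_per_min, lo, hi) {
  steps <- rnorm(n - 1, 0, step_sd_per_min / sqrt(60))
  x <- start + c(0, cumsum(steps))
  # reflect into [lo, hi]
  span <- hi - lo
  x <- (x - lo) %% (2 * span)
  x <- lo + ifelse(x > span, 2 * span - x, x)
  x
}

# 2*pi-periodic pulse templates with a dominant first harmonic
pulse_ecg <- function(phi) {
  d <- ((phi + pi) %% (2 * pi)) - pi
  exp(-d^2 / (2 * 0.45^2))        # Gaussian peak train (QRS-like)
}
pulse_ppg <- function(phi) 0.5 * (1 - cos(phi))  # raised cosine

#' Generate one synthetic subject
#'
#' Deterministic in `(config, subject_seed)`. The respiratory-rate trace is a
#' reflected Gaussian random walk sampled at 1 Hz; the respiratory phase
#' integrates 2*pi*RR(t)/60, the cardiac phase integrates
#' 2*pi*HR*(1 + fm_depth*sin(phi_r))/60, and each channel is
#' `(1 + am_depth*sin(phi_r)) * pulse(phi_c) + bw_amp*sin(phi_r) + noise +
#' artifact_amp*sin(2*pi*artifact_freq*t)` with channel-specific pulse shapes
#' and independent noise draws. `rr_ref` is the exact 1 Hz RR trace used for
#' the modulation, so label error downstream is attributable to the pipeline.
#'
#' @param config A [synthetic_config()].
#' @param subject_seed Integer seed for this subject.
#' @param subject_id Identifier (default derived from the seed).
#' @return A [subject_record()] with `dataset = "synthetic"`.
#' @export
generate_subject <- function(config, subject_seed,
                             subject_id = sprintf("syn_seed%d", subject_seed)) {
  stopifnot(inherits(config, "synthetic_config"))
  with_local_seed(subject_seed, {
    fs <- config$fs
    n <- round(config$duration_s * fs)
    t <- (seq_len(n) - 1) / fs
    hr <- runif(1, config$hr_range[1], config$hr_range[2])
    rr0 <- runif(1, config$rr_range[1], config$rr_range[2])
    age <- runif(1, 18, 90)
    n_rr <- round(config$duration_s * 1)
    rr <- if (config$rr_drift_sd > 0)
      rr_random_walk(n_rr, rr0, config$rr_drift_sd, config$rr_range[1],
                     config$rr_range[2])
    else rep(rr0, n_rr)
    # instantaneous RR on the signal grid (linear interpolation, edge hold)
    rr_t <- stats::approx((seq_len(n_rr) - 1), rr, xout = t, rule = 2)$y
    phi_r <- 2 * pi * cumsum(rr_t / 60) / fs
    phi_c <- 2 * pi * cumsum(hr * (1 + config$fm_depth * sin(phi_r)) / 60) / fs
    resp <- sin(phi_r)
    art <- config$artifact_amp * sin(2 * pi * config$artifact_freq * t)
    make_channel <- function(pulse) {
      (1 + config$am_depth * resp) * pulse +
        config$bw_amp * resp +
        (if (config$noise_sd > 0) rnorm(n, 0, config$noise_sd) else 0) + art
    }
    ecg <- make_channel(pulse_ecg(phi_c))
    ppg <- make_channel(pulse_ppg(phi_c))
    subject_record(subject_id = subject_id, dataset = "synthetic", age = age,
                   ecg = ecg, ppg = ppg, fs_signal = fs, rr_ref = rr,
                   fs_rr = 1)
  })
}

#' Generate a synthetic cohort
#'
#' Subject i (0-based) uses `subject_seed = config$seed + i` and id
#' `"syn_000"`, `"syn_001"`, ... The cohort is a deterministic function of
#' the configuration.
#'
#' @param config A [synthetic_config()].
#' @return List of [subject_record()]s of length `config$n_subjects`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  lapply(seq_len(config$n_subjects) - 1L, function(i)
    generate_subject(config, config$seed + i, sprintf("syn_%03d", i)))
}
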