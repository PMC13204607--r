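#' Simulation configuration
#'
#' Collects every tunable of the synthetic-data generators: cohort
#' distribution parameters, sampling rates, signal amplitudes and noise
#' levels, and the sparse linear feature-to-outcome link used by
#' [simulate_feature_cohort()]. Defaults emulate a quiet laboratory
#' recording of a healthy adult cohort; all magnitudes are simulator
#' conventions and only orderings (e.g. forceful maneuvers louder and
#' shorter than low-effort) are contractual.
#'
#' @param n_subjects Number of subjects.
#' @param mode Maneuver type, `"low_effort"` or `"forceful"`.
#' @param seed Master seed; every stream is derived from it.
#' @param audio_rate Audio sampling rate (Hz, >= 2000).
#' @param imu_rate IMU sampling rate (Hz, >= 20).
#' @param snr_db Sensor signal-to-noise ratio (dB) applied to both
#'   channels; `Inf` disables sensor noise.
#' @param cohort_params See [cohort_params_default()].
#' @param audio_scale Base amplitude of the inspiratory acoustic envelope
#'   (dimensionless full-scale units).
#' @param exp_insp_ratio Expiratory over inspiratory envelope peak (> 1:
#'   expiration is the louder phase at the trachea).
#' @param forceful_gain Amplitude multiplier of forceful over low-effort
#'   maneuvers (default 4).
#' @param highband_gain Relative weight of the 800-1000 Hz tracheal band
#'   added on top of the 50-1000 Hz base band.
#' @param imu_amp Chest-motion half-amplitude (g) in low-effort mode.
#' @param imu_forceful_gain Motion amplitude multiplier for forceful mode.
#' @param drift_amp,drift_period Baseline drift sinusoid amplitude (g) and
#'   period (s) on the IMU.
#' @param artifact_rate Expected motion-artifact spikes per second.
#' @param artifact_amp Artifact spike amplitude (g).
#' @param xy_atten Attenuation of the respiration waveform on the X/Y axes.
#' @param n_cycles_per_subject Breath rows per subject in feature cohorts.
#' @param true_coefficients Named numeric: sparse linear link from features
#'   to the outcome in [simulate_feature_cohort()].
#' @param intercept Outcome intercept (units of the outcome).
#' @param noise_sd Outcome residual SD.
#' @param subject_effect_sd SD of the per-subject random intercept on the
#'   outcome.
#' @param feature_subject_sd SD of the per-subject random intercept shared
#'   by a feature's rows (creates within-subject feature correlation).
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_subjects = 1L,
                              mode = "low_effort",
                              seed = 1L,
                              audio_rate = 8000,
                              imu_rate = 100,
                              snr_db = 20,
                              cohort_params = cohort_params_default(),
                              audio_scale = 0.03,
                              exp_insp_ratio = 1.5,
                              forceful_gain = 4,
                              highband_gain = 0.5,
                              imu_amp = 0.02,
                              imu_forceful_gain = 2,
                              drift_amp = 0.002,
                              drift_period = 25,
                              artifact_rate = 0,
                              artifact_amp = 0.05,
                              xy_atten = 0.3,
                              n_cycles_per_subject = 3L,
                              true_coefficients = NULL,
                              intercept = 0,
                              noise_sd = 0.5,
                              subject_effect_sd = 0,
                              feature_subject_sd = 0.3) {
  check_mode(mode)
  assert_scalar_pos(audio_rate, "audio_rate")
  assert_scalar_pos(imu_rate, "imu_rate")
  if (n_subjects < 1) stop_param("`n_subjects` must be >= 1")
  structure(
    list(n_subjects = as.integer(n_subjects), mode = mode, seed = seed,
         audio_rate = audio_rate, imu_rate = imu_rate, snr_db = snr_db,
         cohort_params = cohort_params, audio_scale = audio_scale,
         exp_insp_ratio = exp_insp_ratio, forceful_gain = forceful_gain,
         highband_gain = highband_gain, imu_amp = imu_amp,
         imu_forceful_gain = imu_forceful_gain, drift_amp = drift_amp,
         drift_period = drift_period, artifact_rate = artifact_rate,
         artifact_amp = artifact_amp, xy_atten = xy_atten,
         n_cycles_per_subject = as.integer(n_cycles_per_subject),
         true_coefficients = true_coefficients, intercept = intercept,
         noise_sd = noise_sd, subject_effect_sd = subject_effect_sd,
         feature_subject_sd = feature_subject_sd),
    class = "simulation_config")
}
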