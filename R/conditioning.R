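# Conditioning stages: raw channels -> smooth 20 Hz envelopes.

#' Condition the IMU Z axis into a respiration envelope
#'
#' Zero-phase low-pass of the Z-axis acceleration (2nd-order Butterworth,
#' 5 Hz by default) to isolate respiration-related motion, followed by
#' moving-median and moving-average smoothing and linear resampling onto
#' the common envelope grid.
#'
#' @param imu An [imu_recording()].
#' @param params A [detection_params()].
#' @return An [envelope()] of kind `"imu_z"`.
#' @export
preprocess_imu <- function(imu, params = detection_params()) {
  rate <- imu$rate
  if (rate <= 2 * params$imu_lowpass)
    stop_param("IMU rate must exceed twice the low-pass cutoff")
  n <- length(imu$az)
  settle <- ceiling(rate / params$imu_lowpass)
  if (n < 3L * settle)
    stop_param("IMU recording too short for stable filtering")
  bf <- signal::butter(params$butter_order,
                       params$imu_lowpass / (rate / 2), type = "low")
  z <- zero_phase_filter(bf, imu$az)
  z <- moving_median(z, round(params$median_window * rate))
  z <- moving_mean(z, round(params$mean_window * rate))
  rs <- resample_uniform(imu$t, z, params$envelope_rate)
  envelope(rs$x, params$envelope_rate, kind = "imu_z", t0 = rs$t[1])
}

#' Band-pass the tracheal audio
#'
#' Zero-phase Butterworth band-pass (50-1000 Hz by default) emphasizing
#' tracheal sounds and removing DC.
#'
#' @param audio An [audio_recording()].
#' @param params A [detection_params()].
#' @return Numeric vector of filtered samples (same length/rate as input).
#' @export
preprocess_audio <- function(audio, params = detection_params()) {
  rate <- audio$rate
  if (rate <= 2000)
    stop_param("audio rate must exceed 2000 Hz")
  if (params$audio_band[2] >= rate / 2)
    stop_param("audio band infeasible at this sampling rate")
  bf <- signal::butter(params$butter_order,
                       params$audio_band / (rate / 2), type = "pass")
  zero_phase_filter(bf, audio$samples)
}

#' Compute the tracheal sound energy (TSEng) envelope
#'
#' TSEng is the natural logarithm of the moving variance of the band-passed
#' audio over a 20 ms centered sliding window (edges handled by shrinking
#' windows; variances floored at `log_floor` before the log). The full-rate
#' log-variance track is decimated to an intermediate 200 Hz grid (the
#' variance window itself is the anti-alias stage), low-passed at 2 Hz with
#' zero phase, median/mean smoothed, and resampled to the envelope rate.
#'
#' @param filtered_audio Output of [preprocess_audio()].
#' @param rate Audio sampling rate (Hz).
#' @param params A [detection_params()].
#' @param t0 Session time of the first sample (s).
#' @return An [envelope()] of kind `"tseng"`.
#' @export
compute_tseng <- function(filtered_audio, rate, params = detection_params(),
                          t0 = 0) {
  w <- round(params$tseng_window * rate)
  if (w < 2) stop_param("tseng_window must span at least 2 samples")
  raw <- log(pmax(moving_var(filtered_audio, w), params$log_floor))
  t_raw <- t0 + (seq_along(raw) - 1L) / rate
  inter_rate <- min(200, rate)
  rs <- resample_uniform(t_raw, raw, inter_rate)
  bf <- signal::butter(params$butter_order,
                       params$tseng_lowpass / (inter_rate / 2), type = "low")
  x <- zero_phase_filter(bf, rs$x)
  x <- moving_median(x, round(params$median_window * inter_rate))
  x <- moving_mean(x, round(params$mean_window * inter_rate))
  out <- resample_uniform(rs$t, x, params$envelope_rate)
  envelope(out$x, params$envelope_rate, kind = "tseng", t0 = out$t[1])
}

# pre-smoothing TSEng track (exposed for moment-level checks)
tseng_raw <- function(filtered_audio, rate, params = detection_params()) {
  w <- round(params$tseng_window * rate)
  if (w < 2) stop_param("tseng_window must span at least 2 samples")
  log(pmax(moving_var(filtered_audio, w), params$log_floor))
}
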