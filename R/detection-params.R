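#' Respiratory phase-detection parameters
#'
#' Tunables of the detection pipeline. Defaults follow the conditioning
#' chain: audio band-passed 50-1000 Hz; tracheal sound energy (TSEng) as
#' the log moving variance over a 20 ms window, low-passed at 2 Hz; IMU-Z
#' low-passed at 5 Hz; both tracks median- and mean-smoothed over 0.5 s and
#' resampled to 20 Hz; extrema detected with a 1.5 s minimum spacing and a
#' prominence threshold of 20% of the envelope interquartile range; IMU
#' minima associated to TSEng minima within a +/-1 s window; sessions kept
#' when at least 3 valid cycles are found.
#'
#' @param audio_band Band-pass edges for the tracheal audio (Hz).
#' @param tseng_window Moving-variance window (s).
#' @param tseng_lowpass TSEng envelope low-pass cutoff (Hz).
#' @param imu_lowpass IMU-Z low-pass cutoff (Hz).
#' @param butter_order Butterworth order for all conditioning filters.
#' @param envelope_rate Common envelope rate after resampling (Hz).
#' @param min_peak_distance Minimum spacing between retained like extrema (s).
#' @param prominence_frac_iqr Prominence threshold as a fraction of the
#'   conditioned envelope's IQR.
#' @param association_window Maximum |IMU minimum - TSEng minimum| gap (s).
#' @param median_window,mean_window Smoothing window lengths (s).
#' @param min_valid_cycles Minimum valid breath cycles to retain a session.
#' @param log_floor Variance floor applied before the TSEng logarithm.
#' @param strict_expiration If `TRUE`, expiration events (IMU maxima) also
#'   require a nearby TSEng feature; by default only inspiration events do.
#' @return A `detection_params` list.
#' @export
detection_params <- function(audio_band = c(50, 1000),
                             tseng_window = 0.020,
                             tseng_lowpass = 2,
                             imu_lowpass = 5,
                             butter_order = 2,
                             envelope_rate = 20,
                             min_peak_distance = 1.5,
                             prominence_frac_iqr = 0.20,
                             association_window = 1.0,
                             median_window = 0.5,
                             mean_window = 0.5,
                             min_valid_cycles = 3L,
                             log_floor = 1e-12,
                             strict_expiration = FALSE) {
  vals <- list(audio_band = audio_band, tseng_window = tseng_window,
               tseng_lowpass = tseng_lowpass, imu_lowpass = imu_lowpass,
               butter_order = as.integer(butter_order),
               envelope_rate = envelope_rate,
               min_peak_distance = min_peak_distance,
               prominence_frac_iqr = prominence_frac_iqr,
               association_window = association_window,
               median_window = median_window, mean_window = mean_window,
               min_valid_cycles = as.integer(min_valid_cycles),
               log_floor = log_floor,
               strict_expiration = isTRUE(strict_expiration))
  num <- unlist(vals[setdiff(names(vals), "strict_expiration")])
  if (any(!is.finite(num)) || any(num <= 0))
    stop_param("all detection parameters must be positive and finite")
  if (audio_band[1] >= audio_band[2])
    stop_param("audio_band must satisfy low < high")
  structure(vals, class = "detection_params")
}
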