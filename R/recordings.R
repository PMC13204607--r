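# Core containers shared by the simulator, the readers and the detection
# pipeline. All times are seconds from session t = 0.

#' Construct an audio recording
#'
#' @param samples Numeric vector of dimensionless amplitudes in [-1, 1].
#' @param rate Sampling rate in Hz.
#' @param t0 Start time in session seconds (default 0).
#' @return An `audio_recording` object.
#' @export
audio_recording <- function(samples, rate, t0 = 0) {
  assert_scalar_pos(rate, "rate")
  samples <- as.numeric(samples)
  if (any(!is.finite(samples))) stop_param("audio samples must be finite")
  structure(list(samples = samples, rate = rate, t0 = t0),
            class = "audio_recording")
}

#' @export
print.audio_recording <- function(x, ...) {
  cat(sprintf("<audio_recording> %d samples @ %g Hz (%.2f s), t0 = %g s\n",
              length(x$samples), x$rate, length(x$samples) / x$rate, x$t0))
  invisible(x)
}

#' Construct a tri-axial IMU recording
#'
#' @param t Strictly increasing time stamps (s).
#' @param ax,ay,az Acceleration per axis (g), equal length to `t`.
#' @param rate Optional nominal rate (Hz); inferred from median time step
#'   when missing.
#' @return An `imu_recording` object.
#' @export
imu_recording <- function(t, ax, ay, az, rate = NULL) {
  n <- length(t)
  if (!(length(ax) == n && length(ay) == n && length(az) == n))
    stop_param("t, ax, ay, az must have equal length")
  if (n > 1L && any(diff(t) <= 0))
    stop_param("IMU time stamps must be strictly increasing")
  if (is.null(rate)) {
    if (n < 2L) stop_param("cannot infer rate from a single sample")
    rate <- 1 / median(diff(t))
  }
  structure(list(t = as.numeric(t), ax = as.numeric(ax), ay = as.numeric(ay),
                 az = as.numeric(az), rate = rate),
            class = "imu_recording")
}

#' @export
print.imu_recording <- function(x, ...) {
  cat(sprintf("<imu_recording> %d samples @ %.4g Hz, t in [%.2f, %.2f] s\n",
              length(x$t), x$rate, x$t[1], x$t[length(x$t)]))
  invisible(x)
}

#' Construct a session
#'
#' Bundles the time-aligned audio and IMU recordings of one maneuver
#' sequence with the subject profile and, when available, the ground-truth
#' breath annotation. Audio and IMU must overlap in time.
#'
#' @param subject_id Subject identifier.
#' @param mode Maneuver type, `"low_effort"` or `"forceful"`.
#' @param audio An [audio_recording()].
#' @param imu An [imu_recording()].
#' @param profile One-row data.frame of subject covariates and reference
#'   spirometry (see [simulate_subject_profiles()]).
#' @param annotation Optional [breath_timeline()] ground truth.
#' @return A `session` object.
#' @export
session <- function(subject_id, mode, audio, imu, profile, annotation = NULL) {
  check_mode(mode)
  stopifnot(inherits(audio, "audio_recording"), inherits(imu, "imu_recording"))
  a_range <- c(audio$t0, audio$t0 + length(audio$samples) / audio$rate)
  i_range <- range(imu$t)
  if (a_range[1] >= i_range[2] || i_range[1] >= a_range[2])
    stop_param("alignment error: audio and IMU time ranges do not overlap")
  if (!is.null(annotation) && !inherits(annotation, "breath_timeline"))
    stop_param("`annotation` must be a breath_timeline")
  structure(list(subject_id = subject_id, mode = mode, audio = audio,
                 imu = imu, profile = profile, annotation = annotation),
            class = "session")
}

#' @export
print.session <- function(x, ...) {
  cat(sprintf("<session> %s (%s): audio %.1f s @ %g Hz, IMU %.1f s @ %.4g Hz%s\n",
              x$subject_id, x$mode,
              length(x$audio$samples) / x$audio$rate, x$audio$rate,
              diff(range(x$imu$t)), x$imu$rate,
              if (is.null(x$annotation)) "" else
                sprintf(", %d annotated cycle(s)", nrow(x$annotation$cycles))))
  invisible(x)
}
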