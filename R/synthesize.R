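# Generative signal models for the simulator. The acoustic model is
# band-limited Gaussian noise (50-1000 Hz, extra energy 800-1000 Hz)
# amplitude-modulated by a smooth per-phase airflow envelope; the chest
# motion model is a sum of cosine ramps between breath events with minima
# at inspiration onsets and maxima at expiration onsets, plus drift, noise
# and optional artifact spikes.

phase_envelope <- function(t, timeline, peak_insp, peak_exp) {
  env <- numeric(length(t))
  cyc <- timeline$cycles
  sound_end <- timeline$exp_sound_end %||% cyc$cycle_end
  for (k in seq_len(nrow(cyc))) {
    ii <- t >= cyc$insp_start[k] & t < cyc$exp_start[k]
    env[ii] <- peak_insp * sin(pi * (t[ii] - cyc$insp_start[k]) /
                                 (cyc$exp_start[k] - cyc$insp_start[k]))^2
    ee <- t >= cyc$exp_start[k] & t < sound_end[k]
    env[ee] <- peak_exp * sin(pi * (t[ee] - cyc$exp_start[k]) /
                                (sound_end[k] - cyc$exp_start[k]))^2
  }
  if (nrow(cyc)) {
    # pre-roll: dying tail of the previous (unannotated) exhalation
    pre <- timeline$pre_roll_end %||% 0
    if (pre > 0) {
      pp <- t < pre
      env[pp] <- pmax(env[pp], peak_exp * cos(pi / 2 * t[pp] / pre)^2)
    }
    # post-roll: onset of the next inhalation at the last cycle_end
    t_post <- cyc$cycle_end[nrow(cyc)]
    dur <- timeline$duration
    if (dur > t_post) {
      qq <- t >= t_post
      env[qq] <- pmax(env[qq], peak_insp *
                        sin(pi / 2 * (t[qq] - t_post) / (dur - t_post))^2)
    }
  }
  env
}

band_noise <- function(n, rate, low, high, order = 4) {
  bf <- signal::butter(order, c(low, high) / (rate / 2), type = "pass")
  zero_phase_filter(bf, rnorm(n))
}

#' Synthesize a tracheal-sound recording
#'
#' Airflow-modulated band-limited noise: a 50-1000 Hz Gaussian carrier
#' (with additional 800-1000 Hz energy mimicking the tracheal band) is
#' multiplied by a smooth envelope that rises within each inspiration and
#' expiration and returns to baseline in pauses. Expiration peaks exceed
#' inspiration peaks; forceful maneuvers are louder than low-effort by
#' `config$forceful_gain`. White sensor noise is added at `config$snr_db`
#' relative to the in-cycle signal RMS.
#'
#' @param timeline A [breath_timeline()].
#' @param config A [simulation_config()].
#' @param seed Seed for the carrier and sensor-noise streams (defaults to
#'   the config seed).
#' @return An [audio_recording()] at `config$audio_rate`.
#' @export
synthesize_tracheal_audio <- function(timeline, config, seed = config$seed) {
  if (config$audio_rate < 2000)
    stop_param("audio_rate must be >= 2000 Hz to represent the 1 kHz band")
  rate <- config$audio_rate
  n <- max(2L, round(timeline$duration * rate))
  t <- (seq_len(n) - 1L) / rate
  gain <- if (timeline$mode == "forceful") config$forceful_gain else 1
  peak_insp <- config$audio_scale * gain
  peak_exp <- peak_insp * config$exp_insp_ratio
  env <- phase_envelope(t, timeline, peak_insp, peak_exp)
  with_seed(seed, {
    carrier <- band_noise(n, rate, 50, 1000) +
      config$highband_gain * band_noise(n, rate, 800, 1000)
    carrier <- carrier / max(sqrt(mean(carrier^2)), 1e-12)
    x <- env * carrier
    in_cycle <- env > 0
    ref_rms <- if (any(in_cycle)) sqrt(mean(x[in_cycle]^2))
               else peak_insp / 2  # empty timeline: nominal reference level
    if (is.finite(config$snr_db)) {
      noise_sd <- ref_rms / 10^(config$snr_db / 20)
      x <- x + rnorm(n, sd = noise_sd)
    }
    audio_recording(x, rate)
  })
}

#' Synthesize a chest-motion IMU recording
#'
#' The Z axis is a smooth respiration waveform interpolated with cosine
#' ramps between breath events so that its minima fall exactly at
#' inspiration onsets and its maxima at expiration onsets, plus sinusoidal
#' baseline drift, white sensor noise (set by `config$snr_db`) and optional
#' exponentially decaying motion-artifact spikes. X/Y axes carry attenuated
#' copies of the clean waveform plus independent noise.
#'
#' @inheritParams synthesize_tracheal_audio
#' @return An [imu_recording()] at `config$imu_rate`.
#' @export
synthesize_imu <- function(timeline, config, seed = config$seed) {
  if (config$imu_rate < 20)
    stop_param("imu_rate must be >= 20 Hz for the conditioning stages")
  rate <- config$imu_rate
  n <- max(2L, round(timeline$duration * rate))
  t <- (seq_len(n) - 1L) / rate
  gain <- if (timeline$mode == "forceful") config$imu_forceful_gain else 1
  A <- config$imu_amp * gain
  cyc <- timeline$cycles
  rest <- -0.3 * A
  if (nrow(cyc)) {
    # open mid-relaxation (descending into the first inspiration onset)
    # and close rising out of the final inspiration onset at cycle_end[n],
    # so first and last annotated events are true interior extrema
    anchor_t <- c(0, rbind(cyc$insp_start, cyc$exp_start),
                  cyc$cycle_end[nrow(cyc)], timeline$duration)
    anchor_v <- c(0.5 * A, rbind(rep(-A, nrow(cyc)), rep(A, nrow(cyc))),
                  -A, rest)
    z <- cosine_interp(anchor_t, anchor_v, t)
  } else {
    z <- rep(rest, n)
  }
  z_clean <- z
  with_seed(seed, {
    if (config$drift_amp > 0)
      z <- z + config$drift_amp *
        sin(2 * pi * t / config$drift_period + runif(1, 0, 2 * pi))
    ref_rms <- max(sqrt(mean(z_clean^2)), 1e-12)
    noise_sd <- if (is.finite(config$snr_db)) ref_rms / 10^(config$snr_db / 20)
                else 0
    if (noise_sd > 0) z <- z + rnorm(n, sd = noise_sd)
    if (config$artifact_rate > 0) {
      n_art <- rpois(1, config$artifact_rate * timeline$duration)
      if (n_art > 0) {
        at <- runif(n_art, 0, timeline$duration)
        sgn <- sample(c(-1, 1), n_art, replace = TRUE)
        for (k in seq_len(n_art)) {
          idx <- which(t >= at[k] & t < at[k] + 0.15)
          z[idx] <- z[idx] + sgn[k] * config$artifact_amp *
            exp(-(t[idx] - at[k]) / 0.03)
        }
      }
    }
    ax <- config$xy_atten * z_clean +
      if (noise_sd > 0) rnorm(n, sd = noise_sd) else 0
    ay <- config$xy_atten * z_clean +
      if (noise_sd > 0) rnorm(n, sd = noise_sd) else 0
    imu_recording(t = t, ax = ax, ay = ay, az = z, rate = rate)
  })
}

# piecewise cosine interpolation through (xk, vk); flat derivative at every
# knot, so interior knots are exact local extrema of the waveform
cosine_interp <- function(xk, vk, x) {
  i <- findInterval(x, xk, rightmost.closed = TRUE)
  i[i < 1L] <- 1L
  i[i >= length(xk)] <- length(xk) - 1L
  s <- (x - xk[i]) / (xk[i + 1L] - xk[i])
  s <- pmin(pmax(s, 0), 1)
  vk[i] + (vk[i + 1L] - vk[i]) * (1 - cos(pi * s)) / 2
}

#' Simulate a full annotated session
#'
#' Draws a breath timeline, synthesizes the audio and IMU channels from it
#' (shared t = 0), and bundles them with the subject profile and the true
#' timeline as ground-truth annotation.
#'
#' @param profile One-row subject profile (see
#'   [simulate_subject_profiles()]).
#' @param mode Maneuver type.
#' @param n_cycles Number of breath cycles.
#' @param config A [simulation_config()].
#' @return A [session()] with `annotation` set.
#' @export
simulate_session <- function(profile, mode = config$mode, n_cycles = 5L,
                             config = simulation_config()) {
  check_mode(mode)
  sid <- as.character(profile$subject_id[1])
  tl <- simulate_breath_timeline(mode, n_cycles,
                                 seed = derive_seed(config$seed, sid, "tl"))
  audio <- synthesize_tracheal_audio(tl, config,
                                     seed = derive_seed(config$seed, sid, "au"))
  imu <- synthesize_imu(tl, config, seed = derive_seed(config$seed, sid, "imu"))
  session(subject_id = sid, mode = mode, audio = audio, imu = imu,
          profile = profile, annotation = tl)
}
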