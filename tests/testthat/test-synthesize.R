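test_that("noise-free audio is silent in the relaxation tails", {
  tl <- simulate_breath_timeline("low_effort", 4, seed = 3)
  cfg <- simulation_config(snr_db = Inf, seed = 3)
  au <- synthesize_tracheal_audio(tl, cfg, seed = 3)
  t <- (seq_along(au$samples) - 1) / au$rate
  in_sound <- rep(FALSE, length(t))
  in_tail <- rep(FALSE, length(t))
  for (k in seq_len(nrow(tl$cycles))) {
    in_sound <- in_sound | (t >= tl$cycles$insp_start[k] &
                              t < tl$exp_sound_end[k])
    # leave a margin after the audible exhalation dies out
    in_tail <- in_tail | (t >= tl$exp_sound_end[k] + 0.1 &
                            t < tl$cycles$cycle_end[k] - 0.1)
  }
  rms <- function(v) sqrt(mean(v^2))
  expect_gt(rms(au$samples[in_sound]), 10 * rms(au$samples[in_tail]))
})

test_that("an empty timeline yields a pure sensor-noise recording", {
  tl <- breath_timeline(
    data.frame(insp_start = numeric(0), exp_start = numeric(0),
               cycle_end = numeric(0)), "forceful", duration = 3)
  au <- synthesize_tracheal_audio(tl, simulation_config(snr_db = 20), seed = 1)
  expect_equal(length(au$samples), 3 * 8000)
  expect_gt(sd(au$samples), 0)
  silent <- synthesize_tracheal_audio(tl, simulation_config(snr_db = Inf),
                                      seed = 1)
  expect_equal(max(abs(silent$samples)), 0)
})

test_that("forceful maneuvers are louder than low-effort on the same geometry", {
  tl <- simulate_breath_timeline("low_effort", 3, seed = 6)
  tl_f <- tl
  tl_f$mode <- "forceful"
  cfg <- simulation_config(snr_db = Inf)
  a_lo <- synthesize_tracheal_audio(tl, cfg, seed = 6)
  a_fo <- synthesize_tracheal_audio(tl_f, cfg, seed = 6)
  expect_gt(max(abs(a_fo$samples)), 2 * max(abs(a_lo$samples)))
})

test_that("audio synthesis rejects rates below the tracheal band", {
  tl <- simulate_breath_timeline("forceful", 2, seed = 1)
  expect_error(
    synthesize_tracheal_audio(tl, simulation_config(audio_rate = 1500)),
    "2000")
})

test_that("clean IMU-Z extrema land on the annotated events", {
  tl <- simulate_breath_timeline("forceful", 4, seed = 9)
  cfg <- simulation_config(snr_db = Inf, drift_amp = 0, artifact_rate = 0)
  imu <- synthesize_imu(tl, cfg, seed = 9)
  z <- imu$az
  n <- length(z)
  mins <- which(z[2:(n - 1)] < z[1:(n - 2)] & z[2:(n - 1)] <= z[3:n]) + 1L
  maxs <- which(z[2:(n - 1)] > z[1:(n - 2)] & z[2:(n - 1)] >= z[3:n]) + 1L
  truth <- annotation_events(tl)
  dt <- 1 / imu$rate
  for (ev in truth$insp)
    expect_lte(min(abs(imu$t[mins] - ev)), dt + 1e-9)
  for (ev in truth$exp)
    expect_lte(min(abs(imu$t[maxs] - ev)), dt + 1e-9)
})

test_that("zero motion amplitude leaves only drift and noise on Z", {
  tl <- simulate_breath_timeline("low_effort", 3, seed = 4)
  cfg <- simulation_config(imu_amp = 0, drift_amp = 0, snr_db = Inf)
  imu <- synthesize_imu(tl, cfg, seed = 4)
  expect_equal(diff(range(imu$az)), 0)
  expect_error(synthesize_imu(tl, simulation_config(imu_rate = 10)), "20")
})

test_that("recordings are pure functions of config and seed", {
  tl <- simulate_breath_timeline("forceful", 3, seed = 2)
  cfg <- simulation_config(snr_db = 15, artifact_rate = 0.1)
  expect_identical(synthesize_imu(tl, cfg, seed = 5),
                   synthesize_imu(tl, cfg, seed = 5))
  expect_identical(synthesize_tracheal_audio(tl, cfg, seed = 5),
                   synthesize_tracheal_audio(tl, cfg, seed = 5))
})

test_that("simulated sessions carry faithful annotations and distinct streams", {
  profs <- simulate_subject_profiles(2, seed = 12)
  cfg <- simulation_config(seed = 12)
  s1 <- simulate_session(profs[1, ], mode = "low_effort", n_cycles = 5,
                         config = cfg)
  s2 <- simulate_session(profs[2, ], mode = "low_effort", n_cycles = 5,
                         config = cfg)
  expect_equal(nrow(s1$annotation$cycles), 5)
  expect_true(all(s1$annotation$cycles$cycle_end <= s1$annotation$duration))
  expect_false(identical(s1$subject_id, s2$subject_id))
  n <- min(length(s1$audio$samples), length(s2$audio$samples))
  expect_false(identical(s1$audio$samples[1:n], s2$audio$samples[1:n]))
  expect_equal(s1$audio$t0, 0)
  expect_equal(s1$imu$t[1], 0)
})
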