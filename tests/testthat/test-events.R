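test_that("IMU minima pair with nearby TSEng minima by the window rule", {
  # within-window match -> inspiration at the IMU extremum time
  p1 <- spiropatch:::greedy_pair(10.0, 10.4, window = 1.0)
  expect_equal(p1$imu_time, 10.0)
  expect_equal(p1$tseng_time, 10.4)
  # nearest TSEng minimum beyond the window -> no event
  expect_equal(nrow(spiropatch:::greedy_pair(10.0, 11.5, window = 1.0)), 0)
  # nearest-first greedy: one TSEng minimum claimed by the closer IMU min
  p3 <- spiropatch:::greedy_pair(c(9.8, 10.3), 10.2, window = 1.0)
  expect_equal(p3$imu_time, 10.3)
})

test_that("event association labels and orders events as specified", {
  rate <- 20
  t <- seq(0, 29.95, by = 1 / rate)
  dip <- function(c) -exp(-((t - c)^2) / (2 * 0.25))
  # IMU: minima at 5 and 15, maxima at 10 and 20
  imu <- envelope(dip(5) + dip(15) - dip(10) - dip(20), rate, kind = "imu_z")
  # TSEng: minima at 5.4 and 24 (the second too far from any IMU minimum)
  ts <- envelope(dip(5.4) + dip(24), rate, kind = "tseng")
  ev <- associate_events(imu, ts)
  expect_equal(ev$label[order(ev$time)], ev$label)
  insp <- ev[ev$label == "inspiration_start", ]
  expect_equal(insp$time, 5, tolerance = 0.1)
  expect_equal(insp$tseng_minimum_time, 5.4, tolerance = 0.1)
  # the 15 s IMU minimum has no TSEng partner -> dropped
  expect_equal(nrow(insp), 1)
  exps <- ev[ev$label == "expiration_start", ]
  expect_equal(sort(exps$time), c(10, 20), tolerance = 0.1)
})

test_that("cycle extraction implements the I-E-I pattern rule", {
  ev <- function(tt, ll) data.frame(
    time = tt, label = ifelse(ll == "I", "inspiration_start",
                              "expiration_start"))
  c1 <- extract_cycles(ev(c(0, 2, 5), c("I", "E", "I")))
  expect_equal(c1, data.frame(insp_start = 0, exp_start = 2, cycle_end = 5))
  c2 <- extract_cycles(ev(c(0, 3, 4, 7), c("I", "I", "E", "I")))
  expect_equal(nrow(c2), 1)
  expect_equal(c2$insp_start, 3)
  expect_equal(nrow(extract_cycles(ev(numeric(0), character(0)))), 0)
})

test_that("cycle extraction equals the pattern oracle on random event strings", {
  set.seed(23)
  ok <- TRUE
  for (rep in 1:200) {
    len <- sample(1:12, 1)
    labs <- sample(c("I", "E"), len, replace = TRUE)
    events <- data.frame(
      time = seq_len(len),
      label = ifelse(labs == "I", "inspiration_start", "expiration_start"))
    got <- extract_cycles(events)
    want <- oracle_cycle_positions(labs)
    ok <- ok && identical(got$insp_start, as.numeric(want)) &&
      identical(got$exp_start, as.numeric(want + 1)) &&
      identical(got$cycle_end, as.numeric(want + 2)) &&
      (nrow(got) < 2 ||
         (all(diff(got$insp_start) > 0) &&
            all(head(got$cycle_end, -1) <= tail(got$insp_start, -1))))
  }
  expect_true(ok)
})

test_that("full phase detection recovers clean annotated sessions", {
  sess <- clean_session()
  det <- clean_detection()
  expect_equal(nrow(det$cycles), 5)
  ann <- sess$annotation$cycles
  expect_equal(det$cycles$insp_start, ann$insp_start, tolerance = 0.5)
  expect_equal(det$cycles$exp_start, ann$exp_start, tolerance = 0.5)
  expect_equal(det$cycles$cycle_end, ann$cycle_end, tolerance = 0.5)
  # purity: identical rerun
  expect_identical(det$cycles, detect_phases(sess)$cycles)
})

test_that("a session with no signal yields no cycles", {
  prof <- simulate_subject_profiles(1, seed = 13)
  cfg <- simulation_config(seed = 13, snr_db = Inf, audio_scale = 0,
                           imu_amp = 0, drift_amp = 0)
  s0 <- simulate_session(prof, mode = "low_effort", n_cycles = 3,
                         config = cfg)
  det <- suppressWarnings(detect_phases(s0))
  expect_equal(nrow(det$cycles), 0)
})

test_that("session retention follows the minimum valid-cycle rule", {
  mk <- function(n) data.frame(insp_start = seq_len(n), exp_start = seq_len(n) + 0.4,
                               cycle_end = seq_len(n) + 0.9)
  res <- list(a = mk(2), b = mk(3), c = mk(0), d = mk(5))
  out <- filter_valid_sessions(res)
  expect_setequal(names(out$retained), c("b", "d"))
  expect_setequal(names(out$rejected), c("a", "c"))
  expect_setequal(c(names(out$retained), names(out$rejected)), names(res))
  expect_equal(unname(out$counts), c(2L, 3L, 0L, 5L))
})
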