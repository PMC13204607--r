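test_that("the feature inventory is exactly 185 fixed names", {
  inv <- feature_inventory()
  expect_length(inv, 185)
  expect_equal(anyDuplicated(inv), 0L)
  mods <- feature_modalities()
  expect_equal(sum(mods == "imu"), 12)
  expect_equal(sum(mods == "acoustic"), 173)
  expect_identical(names(mods), inv)
})

test_that("IMU range features match quantile arithmetic", {
  z <- rep(0.5, 50)
  f0 <- imu_range_features(z, z, z)
  expect_equal(unname(f0), rep(0, 6))
  grid <- 0:100
  f1 <- imu_range_features(grid, grid, grid)
  expect_equal(f1[["imu_ax_p2p"]], 100)
  expect_equal(f1[["imu_ax_p95p5"]], 90)
  set.seed(61)
  for (rep in 1:10) {
    v <- rnorm(40)
    f <- imu_range_features(v, v, v)
    expect_gte(f[["imu_az_p2p"]], f[["imu_az_p95p5"]])
  }
  expect_error(imu_range_features(numeric(0), 1, 1), "empty")
})

test_that("envelope/timing features follow their closed forms", {
  rate <- 20
  tt <- seq(0, 9.95, by = 1 / rate)
  cyc <- data.frame(insp_start = 0, exp_start = 2, cycle_end = 5)
  const <- envelope(rep(-4, length(tt)), rate, kind = "tseng")
  f <- envelope_timing_features(cyc, const, rnorm(100, sd = 0.1),
                                rnorm(200, sd = 0.1), 8000)
  expect_length(f, 17)
  expect_equal(f[["insp_dur_s"]], 2)
  expect_equal(f[["exp_dur_s"]], 3)
  expect_equal(f[["cycle_dur_s"]], 5)
  expect_equal(f[["insp_duty"]], 0.4)
  expect_equal(f[["insp_tseng_mean"]], -4)
  expect_equal(f[["insp_tseng_sd"]], 0)
  expect_equal(f[["insp_tseng_area"]], -4 * (2 - 1 / rate), tolerance = 1e-9)
  # expiratory window repeats the inspiratory window (period = phase length)
  cyc2 <- data.frame(insp_start = 1, exp_start = 4, cycle_end = 7)
  sym <- envelope(-10 + cos(2 * pi * (tt - 1) / 3), rate, kind = "tseng")
  f2 <- envelope_timing_features(cyc2, sym, rnorm(100), rnorm(100), 8000)
  expect_equal(f2[["tseng_area_ratio"]], 1, tolerance = 1e-9)
  cyc3 <- data.frame(insp_start = 8, exp_start = 9, cycle_end = 30)
  expect_error(
    envelope_timing_features(cyc3, const, rnorm(10), rnorm(10), 8000),
    "past")
})

test_that("assembled vectors have exactly the documented 185 keys", {
  det <- clean_detection()
  sess <- clean_session()
  fv <- assemble_feature_vector(det$cycles[1, ], sess, det)
  expect_length(fv, 185)
  expect_identical(names(fv), feature_inventory())
  expect_true(all(is.finite(fv)))
  expect_identical(fv, assemble_feature_vector(det$cycles[1, ], sess, det))
})

test_that("feature tables join covariates/targets and apply the cycle rule", {
  profs <- simulate_subject_profiles(3, seed = 71)
  cfg <- simulation_config(seed = 71, snr_db = 30)
  sessions <- list()
  detections <- list()
  for (i in 1:3) {
    s <- simulate_session(profs[i, ], mode = "low_effort", n_cycles = 3,
                          config = cfg)
    sessions[[s$subject_id]] <- s
    det <- detect_phases(s)
    det$cycles <- s$annotation$cycles  # exact boundaries for schema checks
    detections[[s$subject_id]] <- det
  }
  tab <- build_feature_table(sessions, detections)
  expect_s3_class(tab, "feature_table")
  expect_equal(nrow(tab), 9)
  expect_equal(ncol(tab), 3 + 185 + 6 + 3)
  expect_false(anyNA(tab))
  expect_true(all(tab$sex %in% c(0, 1)))
  # drop one subject below the minimum cycle count: excluded entirely
  short <- detections
  short[[1]]$cycles <- short[[1]]$cycles[1:2, ]
  tab2 <- build_feature_table(sessions, short)
  expect_equal(length(unique(tab2$subject_id)), 2)
  expect_false(names(sessions)[1] %in% tab2$subject_id)
})

test_that("simulated feature cohorts realize the planted linear link", {
  inv <- feature_inventory()
  beta <- setNames(c(2, -1), inv[c(5, 80)])
  cfg <- simulation_config(n_subjects = 9, n_cycles_per_subject = 3,
                           seed = 81, true_coefficients = beta,
                           noise_sd = 0, subject_effect_sd = 0,
                           intercept = 1.5)
  tab <- simulate_feature_cohort(cfg)
  expect_equal(nrow(tab), 27)
  y_hat <- 1.5 + as.matrix(tab[names(beta)]) %*% beta
  expect_equal(tab$fvc_ref, drop(y_hat), tolerance = 1e-12)
  # least-squares on a full-rank subset recovers the coefficients exactly
  fit <- fit_ols(as.matrix(tab[c(names(beta), inv[c(1, 2)])]), tab$fvc_ref)
  expect_equal(unname(fit$coefficients[names(beta)]), c(2, -1),
               tolerance = 1e-9)
  expect_equal(unname(fit$coefficients[inv[1]]), 0, tolerance = 1e-9)
  bad <- simulation_config(true_coefficients = c(not_a_feature = 1))
  expect_error(simulate_feature_cohort(bad), "unknown feature")
})
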