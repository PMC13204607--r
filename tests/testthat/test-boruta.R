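test_that("shadow augmentation permutes copies without touching originals", {
  set.seed(91)
  X <- matrix(rnorm(40 * 6), 40, 6,
              dimnames = list(NULL, paste0("f", 1:6)))
  Xa <- make_shadow_features(X, seed = 3)
  expect_equal(ncol(Xa), 12)
  expect_identical(Xa[, 1:6], X)
  expect_identical(colnames(Xa)[7:12], paste0("shadow_f", 1:6))
  for (j in 1:6)
    expect_equal(sort(Xa[, 6 + j]), sort(X[, j]))
  expect_identical(make_shadow_features(X, seed = 3), Xa)
  expect_error(make_shadow_features(X[1, , drop = FALSE]), "2 rows")
})

test_that("shadow columns are decorrelated from their sources on average", {
  set.seed(92)
  X <- matrix(rnorm(500 * 3), 500, 3, dimnames = list(NULL, paste0("f", 1:3)))
  r <- sapply(1:100, function(sd) {
    Xa <- make_shadow_features(X, seed = sd)
    mean(diag(cor(Xa[, 1:3], Xa[, 4:6])))
  })
  expect_lt(abs(mean(r)), 0.05)
})

test_that("importance ranks a duplicated outcome first and is deterministic", {
  set.seed(93)
  X <- matrix(rnorm(80 * 21), 80, 21, dimnames = list(NULL, paste0("f", 1:21)))
  y <- rnorm(80)
  X[, 21] <- y
  imp <- boruta_importance(X, y, n_trees = 300, seed = 4)
  expect_equal(names(which.max(imp)), "f21")
  expect_identical(imp, boruta_importance(X, y, n_trees = 300, seed = 4))
  # constant outcome: importances defined (near zero), not an error
  imp0 <- boruta_importance(X, rep(1, 80), n_trees = 100, seed = 4)
  expect_true(all(is.finite(imp0)))
})

test_that("Boruta confirms planted signal and partitions the features", {
  confirmed <- logical(3)
  dominates <- logical(3)
  for (k in 1:3) {
    set.seed(100 + k)
    X <- matrix(rnorm(60 * 31), 60, 31,
                dimnames = list(NULL, paste0("f", 1:31)))
    y <- X[, 1] + rnorm(60, sd = 0.33)      # planted feature, R^2 ~ 0.9
    res <- run_boruta(X, y, boruta_config(seed = k))
    confirmed[k] <- "f1" %in% res$confirmed
    dominates[k] <- res$hit_counts[["f1"]] >
      median(res$hit_counts[paste0("f", 2:31)])
    expect_setequal(c(res$confirmed, res$rejected, res$tentative),
                    colnames(X))
    expect_length(intersect(res$confirmed, res$rejected), 0)
    expect_true(all(res$hit_counts <= res$n_iterations_run))
  }
  expect_true(all(confirmed))
  expect_true(all(dominates))
})

test_that("Boruta rejects the bulk of pure-noise features", {
  set.seed(105)
  X <- matrix(rnorm(60 * 50), 60, 50, dimnames = list(NULL, paste0("f", 1:50)))
  y <- rnorm(60)
  res <- run_boruta(X, y, boruta_config(seed = 5))
  expect_gte(length(res$rejected), 40)
  res2 <- run_boruta(X, y, boruta_config(seed = 5))
  expect_identical(res$hit_counts, res2$hit_counts)
  expect_error(run_boruta(X[1:5, ], y[1:5]), "10 rows")
})

test_that("per-group selection keys 6 runs and isolates modality signal", {
  inv <- feature_inventory()
  acoustic_feat <- inv[1]               # an MFCC summary feature
  cfg <- simulation_config(n_subjects = 10, n_cycles_per_subject = 3,
                           seed = 111, feature_subject_sd = 0,
                           true_coefficients = setNames(3, acoustic_feat),
                           noise_sd = 0.3)
  tab <- simulate_feature_cohort(cfg, outcome = "fvc_ref")
  bc <- boruta_config(n_iterations = 25L, n_trees = 150L, seed = 2)
  sel <- select_per_group(tab, bc)
  expect_setequal(
    names(sel$results),
    as.vector(outer(c("acoustic", "imu"),
                    c("fvc_ref", "fev1_ref", "pef_ref"), paste, sep = ".")))
  expect_true(acoustic_feat %in% sel$results[["acoustic.fvc_ref"]]$confirmed)
  expect_false(acoustic_feat %in%
                 unlist(lapply(sel$results[c("imu.fvc_ref", "imu.fev1_ref",
                                             "imu.pef_ref")],
                               function(r) r$confirmed)))
  expect_true(acoustic_feat %in% sel$selected$fvc_ref)
})
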