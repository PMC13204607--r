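make_cohort <- function(seed, n_subjects = 8, n_feat_beta = 2,
                        noise_sd = 0.1, subject_effect_sd = 0) {
  inv <- feature_inventory()
  beta <- setNames(rep(1, n_feat_beta), inv[seq_len(n_feat_beta)])
  simulate_feature_cohort(simulation_config(
    n_subjects = n_subjects, n_cycles_per_subject = 3, seed = seed,
    true_coefficients = beta, noise_sd = noise_sd,
    subject_effect_sd = subject_effect_sd))
}

small_cfg <- function() enet_config(alpha_grid = c(0.5, 1), n_lambda = 10L)

test_that("an intercept-only model predicts the training mean", {
  tab <- make_cohort(131)
  res <- run_loso_cv(tab, "fvc_ref", model = "ols",
                     features = character(0), covariates = FALSE)
  for (s in unique(tab$subject_id)) {
    train_mean <- mean(tab$fvc_ref[tab$subject_id != s])
    got <- res$predictions$y_pred[res$predictions$subject_id == s]
    expect_equal(unname(got), rep(train_mean, 3), tolerance = 1e-12)
  }
})

test_that("held-out targets cannot leak into their own predictions", {
  tab <- make_cohort(132)
  feats <- feature_inventory()[1:6]
  cfg <- small_cfg()
  base <- run_loso_cv(tab, "fvc_ref", model = "enet", features = feats,
                      config = cfg)
  victim <- unique(tab$subject_id)[2]
  tampered <- tab
  tampered$fvc_ref[tampered$subject_id == victim] <-
    tampered$fvc_ref[tampered$subject_id == victim] + 100
  redo <- run_loso_cv(tampered, "fvc_ref", model = "enet", features = feats,
                      config = cfg)
  expect_identical(
    base$predictions$y_pred[base$predictions$subject_id == victim],
    redo$predictions$y_pred[redo$predictions$subject_id == victim])
})

test_that("tuning recovers a strong predictor and is deterministic", {
  hits <- logical(5)
  for (k in 1:5) {
    tab <- make_cohort(140 + k, n_subjects = 10, n_feat_beta = 1,
                       noise_sd = 0.3)
    feats <- feature_inventory()[1:8]
    tn <- tune_in_fold(tab, "fvc_ref", feats, small_cfg())
    hits[k] <- tn$fit$coefficients[[feature_inventory()[1]]] != 0
  }
  expect_gte(sum(hits), 4)
  tab <- make_cohort(150, n_subjects = 6)
  feats <- feature_inventory()[1:4]
  t1 <- tune_in_fold(tab, "fvc_ref", feats, small_cfg())
  t2 <- tune_in_fold(tab, "fvc_ref", feats, small_cfg())
  expect_identical(t1$fit$coefficients, t2$fit$coefficients)
  # a one-point grid is returned untouched
  one <- enet_config(alpha_grid = 0.7, n_lambda = 1L)
  t3 <- tune_in_fold(tab, "fvc_ref", feats, one)
  expect_equal(t3$alpha, 0.7)
  expect_error(tune_in_fold(tab[tab$subject_id %in%
                                  unique(tab$subject_id)[1:2], ],
                            "fvc_ref", feats, small_cfg()), "3 training")
})

test_that("LOSO error approaches the noise floor on a linear cohort", {
  tab <- make_cohort(160, n_subjects = 12, n_feat_beta = 2, noise_sd = 0.2)
  res <- run_loso_cv(tab, "fvc_ref", model = "enet",
                     features = feature_inventory()[1:6],
                     config = small_cfg())
  expect_lt(res$loso_summary$mean_rmse, 2 * 0.2)
  expect_lte(res$training_summary$mean_rmse,
             res$loso_summary$mean_rmse + 0.05)
})

test_that("error summaries implement subject-level RMSE/MAE", {
  p1 <- data.frame(subject_id = "a", y_true = c(1, 1), y_pred = c(2, 0))
  s1 <- summarize_errors(p1)
  expect_equal(s1$per_subject$rmse, 1)
  expect_equal(s1$per_subject$mae, 1)
  p2 <- data.frame(subject_id = "a", y_true = c(1, 1), y_pred = c(1, 3))
  s2 <- summarize_errors(p2)
  expect_equal(s2$per_subject$rmse, sqrt(2))
  expect_equal(s2$per_subject$mae, 1)
  exact <- data.frame(subject_id = rep(c("a", "b"), 2), y_true = 1:4,
                      y_pred = 1:4)
  s3 <- summarize_errors(exact)
  expect_equal(s3$mean_rmse, 0)
  expect_equal(s3$mean_mae, 0)
  set.seed(161)
  rnd <- data.frame(subject_id = rep(letters[1:5], each = 4),
                    y_true = rnorm(20), y_pred = rnorm(20))
  s4 <- summarize_errors(rnd)
  expect_true(all(s4$per_subject$rmse >= s4$per_subject$mae))
  expect_error(summarize_errors(rnd[0, ]), "no predictions")
})
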