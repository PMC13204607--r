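# Leave-one-subject-out evaluation with in-fold tuning and
# standardization; subject-level error aggregation.

model_design <- function(table, features, covariates = TRUE) {
  cols <- c(features, if (covariates) COVARIATE_NAMES)
  X <- as.matrix(as.data.frame(table)[cols])
  if (!length(cols)) X <- matrix(numeric(0), nrow(table), 0)
  X
}

subject_rmse <- function(y, pred, subjects) {
  se <- (y - pred)^2
  vapply(split(se, subjects), function(v) sqrt(mean(v)), numeric(1))
}

#' Tune elastic-net hyperparameters within a training fold
#'
#' Inner leave-one-training-subject-out cross-validation over the
#' (alpha, lambda) grid: for each alpha, a shared lambda path is computed
#' from the full training fold, each inner fold is standardized and fitted
#' on its own training rows (warm starts along the path), and the
#' subject-level RMSE of the inner held-out predictions is averaged over
#' subjects. The (alpha, lambda) minimizing inner RMSE wins, with ties
#' resolved toward larger lambda, then larger alpha (sparser models); the
#' winner is refitted on all training rows.
#'
#' @param table Training rows (a [feature_table()] subset).
#' @param index Target column (`"fvc_ref"`, `"fev1_ref"` or `"pef_ref"`).
#' @param features Selected feature names.
#' @param config An [enet_config()].
#' @param covariates Include the demographic covariates in the design
#'   (default `TRUE`).
#' @return List: `alpha`, `lambda`, `fit` (a `fit_result` trained on all
#'   rows), `inner_rmse` (grid matrix).
#' @export
tune_in_fold <- function(table, index, features, config = enet_config(),
                         covariates = TRUE) {
  subjects <- as.character(table$subject_id)
  subj_ids <- unique(subjects)
  if (length(subj_ids) < 3L)
    stop_param("inner CV undefined with fewer than 3 training subjects")
  X <- model_design(table, features, covariates)
  y <- table[[index]]
  pf <- if (config$unpenalized_covariates)
    as.numeric(!colnames(X) %in% COVARIATE_NAMES) else rep(1, ncol(X))

  st_all <- standardize_stats(X)
  keep_all <- !st_all$constant
  Xs_all <- apply_standardization(X, st_all)[, keep_all, drop = FALSE]
  yc_all <- y - mean(y)

  # per-fold standardization and Gram matrices are alpha-independent:
  # compute them once and reuse across the whole grid
  folds <- lapply(subj_ids, function(s) {
    tr <- subjects != s
    st <- standardize_stats(X[tr, , drop = FALSE])
    keep <- !st$constant
    Xs <- apply_standardization(X[tr, , drop = FALSE], st)[, keep,
                                                           drop = FALSE]
    ytr <- y[tr]
    n_tr <- sum(tr)
    list(tr = tr, te = !tr, st = st, keep = keep, ytr_mean = mean(ytr),
         G = crossprod(Xs) / n_tr,
         b = drop(crossprod(Xs, ytr - mean(ytr))) / n_tr)
  })
  best <- NULL
  inner_rmse <- matrix(NA_real_, length(config$alpha_grid), config$n_lambda)
  for (ai in seq_along(config$alpha_grid)) {
    alpha <- config$alpha_grid[ai]
    lambdas <- lambda_path(Xs_all, yc_all, alpha, config)
    pred <- matrix(NA_real_, nrow(X), length(lambdas))
    for (fd in folds) {
      beta_std <- enet_path_gram(fd$G, fd$b, alpha, lambdas,
                                 pf[fd$keep], config)
      beta <- matrix(0, ncol(X), length(lambdas))
      beta[fd$keep, ] <- beta_std / fd$st$sd[fd$keep]
      icpt <- fd$ytr_mean - drop(crossprod(fd$st$mean, beta))
      pred[fd$te, ] <- sweep(X[fd$te, , drop = FALSE] %*% beta, 2,
                             icpt, `+`)
    }
    rmse_l <- apply(pred, 2, function(p)
      mean(subject_rmse(y, p, subjects)))
    inner_rmse[ai, ] <- rmse_l
    for (li in seq_along(lambdas)) {
      cand <- list(alpha = alpha, lambda = lambdas[li], rmse = rmse_l[li])
      if (is.null(best) || cand$rmse < best$rmse ||
          (cand$rmse == best$rmse &&
           (cand$lambda > best$lambda ||
            (cand$lambda == best$lambda && cand$alpha > best$alpha))))
        best <- cand
    }
  }
  fit <- fit_elastic_net(X, y, best$alpha, best$lambda, config,
                         penalty_factor = pf)
  list(alpha = best$alpha, lambda = best$lambda, fit = fit,
       inner_rmse = inner_rmse)
}

#' Leave-one-subject-out cross-validation
#'
#' All rows of each subject are held out in turn; standardization and
#' hyperparameter tuning happen strictly within each training fold. The
#' training-stage summary refits the selected procedure on all rows and
#' predicts all rows (an optimistic, in-sample benchmark).
#'
#' @param table A [feature_table()].
#' @param index Target column.
#' @param mode Breathing mode to subset (`NULL` keeps all rows).
#' @param model `"enet"` (tuned in-fold) or `"ols"` baseline.
#' @param features Selected feature names entering the design.
#' @param config An [enet_config()].
#' @param covariates Include the demographic covariates in the design
#'   (default `TRUE`); with `covariates = FALSE` and no features the model
#'   is intercept-only.
#' @return List of class `loso_result`: `predictions` (data.frame
#'   `subject_id`, `cycle_id`, `index`, `mode`, `y_true`, `y_pred`),
#'   `loso_summary` and `training_summary` ([summarize_errors()] objects),
#'   `fold_models` (per-subject hyperparameters).
#' @export
run_loso_cv <- function(table, index, mode = NULL, model = c("enet", "ols"),
                        features = character(0), config = enet_config(),
                        covariates = TRUE) {
  model <- match.arg(model)
  df <- as.data.frame(table)
  if (!is.null(mode)) {
    check_mode(mode)
    df <- df[df$mode == mode, , drop = FALSE]
  }
  subjects <- as.character(df$subject_id)
  subj_ids <- unique(subjects)
  if (length(subj_ids) < 3L) stop_param("LOSO-CV needs at least 3 subjects")
  y <- df[[index]]
  preds <- rep(NA_real_, nrow(df))
  fold_models <- list()
  for (s in subj_ids) {
    tr <- subjects != s
    train <- df[tr, , drop = FALSE]
    if (model == "enet") {
      tuned <- tune_in_fold(train, index, features, config, covariates)
      fit <- tuned$fit
      fold_models[[s]] <- list(alpha = tuned$alpha, lambda = tuned$lambda)
    } else {
      fit <- fit_ols(model_design(train, features, covariates),
                     train[[index]])
      fold_models[[s]] <- list()
    }
    preds[!tr] <- predict(fit, df[!tr, , drop = FALSE])
  }
  pred_df <- data.frame(subject_id = subjects, cycle_id = df$cycle_id,
                        index = index, mode = df$mode, y_true = y,
                        y_pred = preds, stringsAsFactors = FALSE)
  loso_sum <- summarize_errors(pred_df, stage = "loso")
  full_fit <- if (model == "enet")
    tune_in_fold(df, index, features, config, covariates)$fit
  else fit_ols(model_design(df, features, covariates), y)
  train_pred <- pred_df
  train_pred$y_pred <- predict(full_fit, df)
  train_sum <- summarize_errors(train_pred, stage = "training")
  structure(list(predictions = pred_df, loso_summary = loso_sum,
                 training_summary = train_sum, fold_models = fold_models,
                 full_fit = full_fit, index = index, mode = mode,
                 model = model),
            class = "loso_result")
}

#' @export
print.loso_result <- function(x, ...) {
  cat(sprintf("<loso_result> %s%s, %s: LOSO RMSE %.3f, training RMSE %.3f\n",
              x$index, if (is.null(x$mode)) "" else paste0(" (", x$mode, ")"),
              x$model, x$loso_summary$mean_rmse,
              x$training_summary$mean_rmse))
  invisible(x)
}

#' Subject-level error aggregation
#'
#' Per-subject RMSE and MAE over that subject's held-out rows, averaged
#' (unweighted) across subjects, with standard errors of the across-subject
#' means.
#'
#' @param preds Prediction data.frame with `subject_id`, `y_true`, `y_pred`
#'   (as produced by [run_loso_cv()]).
#' @param stage `"loso"` or `"training"` (annotation only).
#' @return List of class `error_summary`: `per_subject` (data.frame
#'   `subject_id`, `rmse`, `mae`), `mean_rmse`, `mean_mae`, `se_rmse`,
#'   `se_mae`, `n_subjects`, `stage`.
#' @export
summarize_errors <- function(preds, stage = "loso") {
  if (!nrow(preds)) stop_param("no predictions to summarize")
  err <- preds$y_pred - preds$y_true
  by_subj <- split(err, as.character(preds$subject_id))
  per <- data.frame(
    subject_id = names(by_subj),
    rmse = vapply(by_subj, function(e) sqrt(mean(e^2)), numeric(1)),
    mae = vapply(by_subj, function(e) mean(abs(e)), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  n <- nrow(per)
  structure(list(
    per_subject = per,
    mean_rmse = mean(per$rmse), mean_mae = mean(per$mae),
    se_rmse = if (n > 1) sd(per$rmse) / sqrt(n) else NA_real_,
    se_mae = if (n > 1) sd(per$mae) / sqrt(n) else NA_real_,
    n_subjects = n, stage = stage), class = "error_summary")
}

#' @export
print.error_summary <- function(x, ...) {
  cat(sprintf(
    "<error_summary:%s> %d subject(s): RMSE %.3f (SE %.3f), MAE %.3f (SE %.3f)\n",
    x$stage, x$n_subjects, x$mean_rmse, x$se_rmse, x$mean_mae, x$se_mae))
  invisible(x)
}
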