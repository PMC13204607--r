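# Elastic-net and OLS fitting. The elastic net minimizes
#   (1/2n) ||y - b0 - X b||^2 + lambda (alpha ||b||_1 + (1-alpha)/2 ||b||_2^2)
# by cyclic coordinate descent with soft-thresholding on internally
# standardized predictors; coefficients are returned on the original scale
# and the intercept is unpenalized.

#' Elastic-net configuration
#'
#' @param alpha_grid L1 mixing values in (0, 1].
#' @param n_lambda Penalty-path length (log-spaced from the data-driven
#'   maximum down to `lambda_min_ratio` times it).
#' @param lambda_min_ratio Smallest/largest path lambda; `NULL` (default)
#'   picks 1e-4 when there are more rows than predictors and 1e-2
#'   otherwise (the weakly determined case, where tiny penalties are
#'   ill-conditioned).
#' @param tol Convergence threshold on the maximum coefficient change.
#' @param max_iter Maximum coordinate-descent sweeps per lambda.
#' @param unpenalized_covariates If `TRUE`, the demographic covariates are
#'   excluded from the penalty (penalty factor 0).
#' @param seed Integer seed (grid search itself is deterministic).
#' @return An `enet_config` list.
#' @export
enet_config <- function(alpha_grid = seq(0.1, 1, by = 0.1),
                        n_lambda = 50L, lambda_min_ratio = NULL,
                        tol = 1e-7, max_iter = 1e5,
                        unpenalized_covariates = FALSE, seed = 1L) {
  if (!length(alpha_grid)) stop_param("alpha_grid must be nonempty")
  if (tol <= 0) stop_param("tol must be > 0")
  structure(list(alpha_grid = alpha_grid, n_lambda = as.integer(n_lambda),
                 lambda_min_ratio = lambda_min_ratio, tol = tol,
                 max_iter = as.integer(max_iter),
                 unpenalized_covariates = isTRUE(unpenalized_covariates),
                 seed = seed),
            class = "enet_config")
}

# standardization statistics: mean and population SD per column; constant
# columns get SD surrogate 1 and are flagged (their coefficients are
# forced to 0 by a zero "keep" mask)
standardize_stats <- function(X) {
  mu <- colMeans(X)
  sdv <- sqrt(colMeans(sweep(X, 2, mu)^2))
  constant <- sdv <= 0
  sdv[constant] <- 1
  list(mean = mu, sd = sdv, constant = constant)
}

apply_standardization <- function(X, st) {
  sweep(sweep(X, 2, st$mean), 2, st$sd, `/`)
}

new_fit_result <- function(intercept, coefficients, chosen_alpha = NA_real_,
                           chosen_lambda = NA_real_, standardization = NULL,
                           model = "enet") {
  structure(list(intercept = intercept, coefficients = coefficients,
                 chosen_alpha = chosen_alpha, chosen_lambda = chosen_lambda,
                 standardization = standardization, model = model),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  nz <- sum(x$coefficients != 0)
  cat(sprintf("<fit_result:%s> intercept %.4g, %d/%d nonzero coefficient(s)",
              x$model, x$intercept, nz, length(x$coefficients)))
  if (!is.na(x$chosen_lambda))
    cat(sprintf(", alpha = %.2g, lambda = %.4g", x$chosen_alpha,
                x$chosen_lambda))
  cat("\n")
  invisible(x)
}

#' Predict from a fitted model
#'
#' @param object A `fit_result`.
#' @param newdata Matrix or data.frame containing the model's feature
#'   columns.
#' @param ... Unused.
#' @return Numeric predictions.
#' @export
predict.fit_result <- function(object, newdata, ...) {
  feats <- names(object$coefficients)
  if (!length(feats)) return(rep(object$intercept, nrow(newdata)))
  X <- as.matrix(as.data.frame(newdata)[feats])
  drop(object$intercept + X %*% object$coefficients)
}

#' Ordinary least squares baseline
#'
#' Unregularized linear fit with intercept. Rank-deficient designs fall
#' back to the minimum-norm solution with a warning.
#'
#' @param X Feature matrix (may have zero columns: intercept-only model).
#' @param y Outcome.
#' @return A `fit_result` with `model = "ols"`.
#' @export
fit_ols <- function(X, y) {
  X <- as.matrix(X)
  if (is.null(colnames(X)) && ncol(X))
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (!ncol(X))
    return(new_fit_result(mean(y), setNames(numeric(0), character(0)),
                          model = "ols"))
  Xi <- cbind(`(Intercept)` = 1, X)
  qr_fit <- qr(Xi)
  if (qr_fit$rank < ncol(Xi)) {
    warning("rank-deficient design: returning the minimum-norm solution",
            call. = FALSE)
    sv <- svd(Xi)
    pos <- sv$d > max(sv$d) * 1e-10
    coefs <- sv$v[, pos, drop = FALSE] %*%
      ((t(sv$u[, pos, drop = FALSE]) %*% y) / sv$d[pos])
    coefs <- drop(coefs)
  } else {
    coefs <- qr.coef(qr_fit, y)
  }
  new_fit_result(coefs[1], setNames(coefs[-1], colnames(X)), model = "ols")
}

# data-driven lambda path (on the standardized scale)
lambda_path <- function(X_std, y_centered, alpha, config) {
  n <- length(y_centered)
  a <- max(alpha, 1e-3)
  lmax <- max(abs(crossprod(X_std, y_centered))) / (n * a)
  lmax <- max(lmax, 1e-10)
  ratio <- config$lambda_min_ratio %||%
    (if (n > ncol(X_std)) 1e-4 else 1e-2)
  exp(seq(log(lmax), log(lmax * ratio), length.out = config$n_lambda))
}

# path solver in Gram space; returns standardized-scale coefficients p x L
enet_path_gram <- function(G, b, alpha, lambdas, penalty_factor, config) {
  res <- .enet_path_gram_cpp(G, b, alpha, lambdas, penalty_factor,
                             config$tol, config$max_iter)
  if (!all(res$converged))
    stop_param(sprintf(
      "elastic net did not converge at max_iter (last max change %.3g)",
      max(res$last_change[!res$converged])))
  res$beta
}

# core path solver on pre-standardized data; returns standardized-scale
# coefficient matrix p x L
enet_path_std <- function(X_std, y_centered, alpha, lambdas, penalty_factor,
                          config) {
  n <- length(y_centered)
  G <- crossprod(X_std) / n
  b <- drop(crossprod(X_std, y_centered)) / n
  enet_path_gram(G, b, alpha, lambdas, penalty_factor, config)
}

#' Fit an elastic net at fixed hyperparameters
#'
#' Predictors are standardized internally (training statistics; constant
#' columns get coefficient 0), the outcome is centered, and the
#' coordinate-descent solution is returned de-standardized with an
#' unpenalized intercept.
#'
#' @param X Feature matrix.
#' @param y Outcome.
#' @param alpha L1 mixing parameter in (0, 1].
#' @param lambda Penalty strength (>= 0); `lambda = 0` reproduces OLS on
#'   full-rank designs.
#' @param config An [enet_config()].
#' @param penalty_factor Optional per-column penalty multipliers
#'   (default 1 for every column).
#' @return A `fit_result`.
#' @export
fit_elastic_net <- function(X, y, alpha, lambda, config = enet_config(),
                            penalty_factor = NULL) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (!ncol(X))
    return(new_fit_result(mean(y), setNames(numeric(0), character(0)),
                          chosen_alpha = alpha, chosen_lambda = lambda))
  st <- standardize_stats(X)
  keep <- !st$constant
  Xs <- apply_standardization(X, st)[, keep, drop = FALSE]
  yc <- y - mean(y)
  pf <- penalty_factor %||% rep(1, ncol(X))
  beta_std <- setNames(numeric(ncol(X)), colnames(X))
  if (any(keep)) {
    b <- enet_path_std(Xs, yc, alpha, lambda, pf[keep], config)
    beta_std[keep] <- b[, 1]
  }
  beta <- beta_std / st$sd
  intercept <- mean(y) - sum(beta * st$mean)
  new_fit_result(intercept, beta, chosen_alpha = alpha,
                 chosen_lambda = lambda, standardization = st)
}
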