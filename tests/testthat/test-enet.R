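test_that("the unpenalized limit matches ordinary least squares", {
  set.seed(121)
  for (rep in 1:5) {
    X <- matrix(rnorm(30 * 5), 30, 5)
    y <- X %*% runif(5, -2, 2) + rnorm(30)
    en <- fit_elastic_net(X, y, alpha = runif(1, 0.1, 1), lambda = 0)
    ols <- fit_ols(X, y)
    expect_equal(en$coefficients, ols$coefficients, tolerance = 1e-6)
    expect_equal(en$intercept, ols$intercept, tolerance = 1e-6)
  }
})

test_that("OLS matches the normal-equation oracle and handles degeneracy", {
  set.seed(122)
  X <- matrix(rnorm(20 * 5), 20, 5, dimnames = list(NULL, paste0("x", 1:5)))
  y <- rnorm(20)
  fit <- fit_ols(X, y)
  Xi <- cbind(1, X)
  beta <- solve(crossprod(Xi), crossprod(Xi, y))
  expect_equal(unname(c(fit$intercept, fit$coefficients)),
               unname(drop(beta)), tolerance = 1e-9)
  # interpolation: zero residuals when y is exactly linear
  y2 <- drop(X %*% 1:5) + 2
  fit2 <- fit_ols(X, y2)
  expect_lt(max(abs(predict(fit2, as.data.frame(X)) - y2)), 1e-9)
  # constant column: slope absorbed into the intercept
  Xc <- cbind(const = rep(2, 20))
  expect_warning(fit3 <- fit_ols(Xc, y), "rank")
  expect_equal(unname(predict(fit3, data.frame(const = 2))[1]), mean(y),
               tolerance = 1e-9)
})

test_that("penalties at or above lambda_max zero out every slope", {
  set.seed(123)
  X <- matrix(rnorm(40 * 6), 40, 6)
  y <- X[, 1] * 2 + rnorm(40)
  st <- spiropatch:::standardize_stats(X)
  Xs <- spiropatch:::apply_standardization(X, st)
  alpha <- 0.5
  lmax <- max(abs(crossprod(Xs, y - mean(y)))) / (40 * alpha)
  at_max <- fit_elastic_net(X, y, alpha, lmax * (1 + 1e-10))
  expect_true(all(at_max$coefficients == 0))
  expect_equal(at_max$intercept, mean(y))
  below <- fit_elastic_net(X, y, alpha, lmax * 0.9)
  expect_gt(sum(below$coefficients != 0), 0)
})

test_that("orthonormal designs reproduce the soft-threshold closed form", {
  set.seed(124)
  n <- 60; p <- 6
  raw <- scale(matrix(rnorm(n * p), n, p), center = TRUE, scale = FALSE)
  Q <- qr.Q(qr(raw))                 # mean-zero orthonormal columns
  X <- sqrt(n) * Q                   # X'X / n = I, per-column pop. SD 1
  y <- rnorm(n)
  b_ols <- drop(crossprod(X, y - mean(y))) / n
  for (alpha in c(0.3, 1)) {
    lam <- 0.6 * median(abs(b_ols))
    fit <- fit_elastic_net(X, y, alpha, lam)
    soft <- sign(b_ols) * pmax(abs(b_ols) - lam * alpha, 0)
    expect_equal(unname(fit$coefficients), soft / (1 + lam * (1 - alpha)),
                 tolerance = 1e-6)
  }
})

test_that("the pure-lasso path agrees with glmnet exactly", {
  skip_if_not_installed("glmnet")
  set.seed(125)
  X <- matrix(rnorm(60 * 10), 60, 10)
  y <- X[, 1] * 2 - X[, 3] + rnorm(60)
  lam <- 0.25
  g <- glmnet::glmnet(X, y, alpha = 1, lambda = c(1, 0.5, lam),
                      standardize = TRUE, thresh = 1e-14)
  bg <- as.numeric(coef(g, s = lam, exact = TRUE, x = X, y = y))
  f <- fit_elastic_net(X, y, 1, lam)
  expect_equal(unname(f$coefficients), bg[-1], tolerance = 1e-7)
  expect_equal(f$intercept, bg[1], tolerance = 1e-7)
})

test_that("mixed penalties reach at least glmnet's objective value", {
  skip_if_not_installed("glmnet")
  set.seed(126)
  X <- matrix(rnorm(60 * 10), 60, 10)
  y <- X[, 1] * 2 + rnorm(60)
  lam <- 0.3; alpha <- 0.6
  st <- spiropatch:::standardize_stats(X)
  Xs <- spiropatch:::apply_standardization(X, st)
  obj <- function(b0, b_orig) {
    bs <- b_orig * st$sd             # penalty applies on standardized scale
    mean((y - b0 - X %*% b_orig)^2) / 2 +
      lam * (alpha * sum(abs(bs)) + (1 - alpha) / 2 * sum(bs^2))
  }
  g <- glmnet::glmnet(X, y, alpha = alpha, lambda = c(1, 0.5, lam),
                      standardize = TRUE, thresh = 1e-14)
  bg <- as.numeric(coef(g, s = lam, exact = TRUE, x = X, y = y))
  f <- fit_elastic_net(X, y, alpha, lam)
  expect_lte(obj(f$intercept, unname(f$coefficients)),
             obj(bg[1], bg[-1]) + 1e-8)
})

test_that("constant predictors get zero coefficients, not NaNs", {
  set.seed(127)
  X <- cbind(a = rnorm(30), flat = rep(3, 30), b = rnorm(30))
  y <- X[, "a"] + rnorm(30, sd = 0.1)
  f <- fit_elastic_net(X, y, 0.5, 0.01)
  expect_equal(unname(f$coefficients["flat"]), 0)
  expect_true(all(is.finite(c(f$intercept, f$coefficients))))
})
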