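test_that("check loss has the two asymmetric branches and vanishes only at zero", {
  expect_equal(check_loss(2, 0.95), 1.9)
  expect_equal(check_loss(-2, 0.95), 0.1)
  expect_equal(check_loss(0, 0.3), 0)
  u <- seq(-5, 5, by = 0.25)
  expect_true(all(check_loss(u, 0.7) >= 0))
  expect_identical(which(check_loss(u, 0.7) == 0), which(u == 0))
  expect_error(check_loss(1, 0), "tau")
  expect_error(check_loss(1, 1.2), "tau")
})

test_that("observation sets validate their invariants", {
  obs <- observation_set(c(1, 2, 3), x = c(4, 5, 6))
  expect_equal(obs$X[, 1], rep(1, 3), ignore_attr = TRUE)
  expect_equal(obs$p, 2L)
  expect_error(observation_set(c(1, NA)), "missing")
  expect_error(observation_set(1:3, x = c(1, 2)), "rows")
  df <- data.frame(a = 1:4, b = (1:4)^2)
  obs2 <- as_observation_set(df, response = "a", covariates = "b")
  expect_equal(obs2$n, 4L)
  expect_error(as_observation_set(df, response = "zz"), "zz")
})

test_that("exact interpolation and tiny instances are solved exactly", {
  obs <- observation_set(c(0, 1), x = c(0, 1))
  fit <- fit_quantile_regression(obs, 0.5)
  expect_equal(unname(coef(fit)), c(0, 1), tolerance = 1e-10)
  expect_lt(fit$objective, 1e-12)

  obs3 <- observation_set(c(1, 2, 10), x = c(1, 2, 3))
  fit3 <- fit_quantile_regression(obs3, 0.5)
  oracle <- qr_brute_force(obs3$X, obs3$y, 0.5)
  expect_equal(fit3$objective, oracle$objective, tolerance = 1e-10)
  expect_equal(unname(coef(fit3)), oracle$beta, tolerance = 1e-8)
})

test_that("constant weights do not change the minimizer and scale the objective", {
  set.seed(101)
  obs <- observation_set(rnorm(40), x = matrix(rnorm(80), 40))
  f1 <- fit_quantile_regression(obs, 0.8)
  fc <- fit_quantile_regression(obs, 0.8,
          weight_vector(rep(3.7, 40), "density_oracle"))
  expect_equal(coef(fc), coef(f1), tolerance = 1e-9)
  expect_equal(fc$objective, 3.7 * f1$objective, tolerance = 1e-9)
})

test_that("LP objective matches brute-force vertex enumeration on random instances", {
  set.seed(2024)
  for (rep in 1:30) {
    n <- sample(5:12, 1)
    p <- sample(2:3, 1)
    X <- cbind(1, matrix(rnorm(n * (p - 1)), n))
    y <- rnorm(n, sd = 2)
    tau <- runif(1, 0.1, 0.9)
    w <- runif(n, 0.5, 2)
    obs <- observation_set(y, X[, -1, drop = FALSE])
    fit <- fit_quantile_regression(obs, tau, weight_vector(w, "density_oracle"))
    oracle <- qr_brute_force(X, y, tau, w)
    expect_equal(fit$objective, oracle$objective, tolerance = 1e-8)
  }
})

test_that("fits agree with an independent quantile regression solver", {
  skip_if_not_installed("quantreg")
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(30:120, 1)
    x <- matrix(rexp(n * 2), n)
    y <- 1 + x[, 1] - 0.5 * x[, 2] + rt(n, df = 3)
    tau <- runif(1, 0.05, 0.95)
    w <- runif(n, 0.1, 2)
    obs <- observation_set(y, x)
    fit <- fit_quantile_regression(obs, tau, weight_vector(w, "density_oracle"))
    ref <- quantreg::rq.fit.br(obs$X * w, y * w, tau = tau)
    obj_ref <- sum(w * check_loss(y - drop(obs$X %*% ref$coefficients), tau))
    expect_equal(fit$objective, obj_ref, tolerance = 1e-9)
  }
})

test_that("fits are equivariant to response scaling and regressor shifts", {
  set.seed(33)
  for (rep in 1:10) {
    n <- 25
    x <- rnorm(n)
    y <- rnorm(n)
    tau <- runif(1, 0.2, 0.8)
    b0 <- coef(fit_quantile_regression(observation_set(y, x), tau))
    cs <- runif(1, 0.5, 4)
    b_scaled <- coef(fit_quantile_regression(observation_set(cs * y, x), tau))
    expect_equal(unname(b_scaled), unname(cs * b0), tolerance = 1e-7)
    a <- runif(1, -2, 2)
    b_shift <- coef(fit_quantile_regression(observation_set(y, x + a), tau))
    expect_equal(unname(b_shift[2]), unname(b0[2]), tolerance = 1e-7)
    expect_equal(unname(b_shift[1]), unname(b0[1] - a * b0[2]), tolerance = 1e-7)
  }
})

test_that("residual signs satisfy quantile coverage and the subgradient condition", {
  set.seed(55)
  for (rep in 1:10) {
    n <- 60
    obs <- observation_set(rt(n, 3), x = rnorm(n))
    tau <- runif(1, 0.1, 0.9)
    fit <- fit_quantile_regression(obs, tau)
    n_neg <- sum(fit$residuals < -1e-9)
    n_nonpos <- sum(fit$residuals <= 1e-9)
    expect_lte(n_neg, tau * n)
    expect_gte(n_nonpos, tau * n)
    expect_true(subgradient_ok(obs, fit))
  }
})

test_that("degenerate designs are flagged and impossible fits error", {
  obs <- observation_set(1:5, x = cbind(a = 1:5, b = 2 * (1:5)))
  fit <- fit_quantile_regression(obs, 0.5)
  expect_identical(fit$status, "rank_deficient")
  expect_error(fit_quantile_regression(observation_set(1:2, x = cbind(1:2, 3:4)), 0.5),
               "observations")
  expect_error(fit_quantile_regression(observation_set(1:5, x = 1:5), 1.5), "tau")
})

test_that("inverse-norm weights match direct arithmetic and normalize", {
  expect_equal(as.numeric(norm_weights(observation_set(c(1, 2), x = c(2, 2)))),
               c(0.5, 0.5))
  expect_equal(as.numeric(norm_weights(observation_set(c(1, 2), x = c(1, 3)))),
               c(0.75, 0.25))
  set.seed(8)
  obs <- observation_set(rnorm(15), x = matrix(rnorm(30), 15))
  expect_equal(sum(norm_weights(obs)), 1)
  expect_equal(sum(norm_weights(obs, include_intercept = TRUE)), 1)
  # intercept-inclusive norms are bounded by 1 from below
  wi <- norm_weights(obs, include_intercept = TRUE)
  expect_true(all(is.finite(wi) & wi > 0))
  obs0 <- observation_set(c(1, 2), x = c(0, 1))
  expect_error(norm_weights(obs0), "1")
})

test_that("least-squares baseline solves the normal equations", {
  obs <- observation_set(2 + 3 * (1:6), x = 1:6)
  expect_equal(unname(fit_least_squares(obs)), c(2, 3), tolerance = 1e-10)
  obs2 <- observation_set(c(0, 1, 0), x = c(0, 1, 2))
  expect_equal(unname(fit_least_squares(obs2)), c(1 / 3, 0), tolerance = 1e-10)
  set.seed(4)
  obs3 <- observation_set(rnorm(20), x = matrix(rnorm(40), 20))
  beta <- fit_least_squares(obs3)
  res <- obs3$y - drop(obs3$X %*% beta)
  expect_equal(drop(crossprod(obs3$X, res)), rep(0, 3),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_error(fit_least_squares(observation_set(1:4, x = cbind(1:4, 2 * (1:4)))),
               "rank")
})

test_that("oracle-weighted estimator covariance is near the asymptotic sandwich", {
  # tau(1-tau) D0^{-1} with D0 = E[f^2 x x'] under Pareto(3) regressors;
  # E[1/x] = 3/4, E[1/x^2] = 3/5 give D0 = c^2 [[3/5, 3/4], [3/4, 1]]
  tau <- 0.9
  model <- bvpareto_model(3)
  cc <- 4 * (1 - tau)^(5 / 4)
  D0 <- cc^2 * matrix(c(3 / 5, 3 / 4, 3 / 4, 1), 2)
  V_theory <- tau * (1 - tau) * solve(D0)
  n <- 2000
  truth <- bvpareto_true_line(tau, model)
  set.seed(61)
  draws <- t(replicate(150, {
    s <- bvpareto_sample(n, model)
    coef(fit_quantile_regression(s, tau, oracle_weights(s, tau, model)))
  }))
  V_emp <- stats::cov(sqrt(n) * draws)
  ratio <- diag(V_emp) / diag(V_theory)
  expect_true(all(ratio > 0.5 & ratio < 2))
})
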