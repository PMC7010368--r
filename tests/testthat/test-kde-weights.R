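test_that("rule-of-thumb bandwidth matches its closed form", {
  expect_equal(bandwidth_optimal(1, 2), 1)
  expect_equal(bandwidth_optimal(1, 1), (4 / 3)^(1 / 5), tolerance = 1e-12)
  expect_equal(bandwidth_optimal(32, 1), (4 / 3)^(1 / 5) * 32^(-1 / 5),
               tolerance = 1e-12)
  expect_error(bandwidth_optimal(0, 1), "positive")
})

test_that("whitened KDE matches kernel arithmetic and a naive double loop", {
  # single point, unit covariance: kernel height at zero distance
  h <- 0.4
  expect_equal(mv_kde(matrix(3), matrix(3), h = h, S = matrix(1)),
               (2 * pi)^(-1 / 2) / h)
  # two points symmetric about the query contribute equally
  d2 <- mv_kde(matrix(c(-1, 1)), matrix(0), h = 1, S = matrix(1))
  d1 <- mv_kde(matrix(1), matrix(0), h = 1, S = matrix(1))
  expect_equal(d2, d1)
  set.seed(19)
  D <- matrix(rnorm(40), 20, 2)
  q <- matrix(rnorm(12), 6, 2)
  h <- bandwidth_optimal(20, 2)
  expect_equal(mv_kde(D, q, h = h), kde_double_loop(D, q, h), tolerance = 1e-12)
  expect_error(mv_kde(cbind(1:5, 1:5), matrix(c(1, 1), 1)), "singular")
})

test_that("KDE integrates to one and its error shrinks with sample size", {
  set.seed(23)
  x <- rnorm(400)
  grid <- seq(-6, 6, length.out = 1200)
  dens <- mv_kde(matrix(x), matrix(grid), h = bandwidth_optimal(400, 1))
  expect_equal(sum(dens) * diff(grid)[1], 1, tolerance = 1e-2)
  ise <- sapply(c(100, 1000), function(n) {
    mean(replicate(8, {
      xs <- rnorm(n)
      d <- mv_kde(matrix(xs), matrix(grid), h = bandwidth_optimal(n, 1))
      sum((d - dnorm(grid))^2) * diff(grid)[1]
    }))
  })
  expect_lt(ise[2], ise[1])
})

test_that("conditional cdf is a proper, monotone cdf that flattens to the marginal", {
  obs <- observation_set(rep(4, 12), x = rnorm(12))
  expect_equal(conditional_cdf(obs, 0, c(3.9, 4, 5)), c(0, 1, 1))
  set.seed(31)
  obs2 <- observation_set(rnorm(40), x = rnorm(40))
  ys <- sort(obs2$y)
  Fhat <- conditional_cdf(obs2, 0.3, ys, h = 1e6)
  expect_equal(Fhat, stats::ecdf(obs2$y)(ys), tolerance = 1e-9)
  # monotone in y at several covariate points
  for (x0 in c(-1, 0, 2)) {
    Fv <- conditional_cdf(obs2, x0, ys)
    expect_true(all(diff(Fv) >= -1e-12))
    expect_true(all(Fv >= 0 & Fv <= 1))
  }
  # three-point toy against a hand-computed Nadaraya-Watson ratio
  toy <- observation_set(c(1, 2, 3), x = c(0, 1, 2))
  h <- 0.8
  sdx <- stats::sd(c(0, 1, 2))
  kw <- exp(-((c(0, 1, 2) - 1) / sdx)^2 / (2 * h^2))
  expect_equal(conditional_cdf(toy, 1, 2.5, h = h), sum(kw[1:2]) / sum(kw),
               tolerance = 1e-12)
})

test_that("conditional quantile inverts the estimated cdf over the sample grid", {
  obs <- observation_set(rep(7, 15), x = rnorm(15))
  expect_equal(conditional_quantile_est(obs, 0, 0.4), 7)
  set.seed(37)
  obs2 <- observation_set(rt(25, 4), x = rnorm(25))
  med <- conditional_quantile_est(obs2, 0, 0.5, h = 1e6)
  ys <- sort(obs2$y)
  expect_equal(med, ys[which(seq_along(ys) / 25 >= 0.5)[1]])
  # exhaustive scan oracle on a toy set
  toy <- observation_set(c(5, 1, 9), x = c(-1, 0, 1))
  for (tau in c(0.2, 0.5, 0.9)) {
    est <- conditional_quantile_est(toy, 0.5, tau, h = 1)
    Fv <- conditional_cdf(toy, 0.5, sort(toy$y), h = 1)
    expect_equal(est, sort(toy$y)[which(Fv >= tau - 1e-12)[1]])
  }
})

test_that("density weights recompute as the joint/marginal KDE ratio", {
  set.seed(41)
  obs <- observation_set(rnorm(12, sd = 2), x = rnorm(12))
  w <- density_weights(obs, 0.6)
  expect_s3_class(w, "weight_vector")
  expect_identical(attr(w, "kind"), "density_kde")
  expect_true(all(as.numeric(w) > 0 & is.finite(as.numeric(w))))
  xi <- attr(w, "xi_hat")
  Z <- obs$X[, 2, drop = FALSE]
  f_joint <- mv_kde(cbind(obs$y, Z), cbind(xi, Z), h = bandwidth_optimal(12, 2))
  f_marg <- mv_kde(Z, Z, h = bandwidth_optimal(12, 1))
  expect_equal(as.numeric(w), f_joint / f_marg, tolerance = 1e-12)
  expect_error(density_weights(observation_set(rnorm(5), x = rnorm(5)), 0.5), "10")
  expect_error(density_weights(observation_set(rnorm(12), x = rep(2, 12)), 0.5),
               "constant")
})

test_that("estimated weights track the oracle better as the sample grows", {
  model <- bvpareto_model(3)
  corr_at <- function(n, seeds) {
    mean(sapply(seeds, function(sd) {
      s <- bvpareto_sample(n, model, seed = sd)
      w <- density_weights(s, 0.95)
      stats::cor(as.numeric(w), as.numeric(oracle_weights(s, 0.95, model)),
                 method = "spearman")
    }))
  }
  seeds <- 1:6
  expect_gt(corr_at(1500, seeds), corr_at(200, seeds) + 0.2)
})
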