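#' Rule-of-thumb bandwidth for a multivariate normal kernel
#'
#' The normal-reference optimal window width
#' \eqn{\hat{h}_{opt} = A(K)\, n^{-1/(d+4)}} with
#' \eqn{A(K) = \{4/(d+2)\}^{1/(d+4)}}, intended for whitened data (unit
#' covariance); the whitening is supplied by the Fukunaga estimator itself.
#'
#' @param n Sample size (`>= 1`).
#' @param d Data dimension (`>= 1`).
#' @return Positive bandwidth scalar.
#' @examples
#' bandwidth_optimal(1, 2)    # exactly 1
#' bandwidth_optimal(32, 1)   # (4/3)^(1/5) * 32^(-1/5)
#' @export
bandwidth_optimal <- function(n, d) {
  if (n < 1L || d < 1L) stop("n and d must be positive integers")
  (4 / (d + 2))^(1 / (d + 4)) * n^(-1 / (d + 4))
}

#' Whitened multivariate kernel density estimate (Fukunaga form)
#'
#' \deqn{\hat{f}(x) = \frac{(\det S)^{-1/2}}{n h^d} \sum_i
#'   k\{(x - X_i)^T S^{-1} (x - X_i) / h^2\},}
#' with \eqn{k(u) = (2\pi)^{-d/2} e^{-u/2}} the normal kernel profile and
#' `S` the sample covariance of the data (denominator `n - 1`). The
#' covariance whitening makes a single scalar bandwidth meaningful for
#' correlated, differently scaled coordinates.
#'
#' @param data Numeric matrix `n x d` (a vector is taken as `d = 1`).
#' @param query Matrix of evaluation points (`m x d`) or a single
#'   `d`-vector.
#' @param h Bandwidth; default [bandwidth_optimal()] for the data's `n`
#'   and `d`.
#' @param S Covariance matrix used for whitening; default the sample
#'   covariance of `data`. Must be symmetric positive definite.
#' @return Numeric vector of density values at the query points.
#' @export
mv_kde <- function(data, query, h = NULL, S = NULL) {
  if (!is.matrix(data)) data <- matrix(data, ncol = 1L)
  n <- nrow(data); d <- ncol(data)
  if (is.null(h)) h <- bandwidth_optimal(n, d)
  if (h <= 0) stop("bandwidth must be positive")
  if (is.null(S)) {
    if (n < 2L) S <- diag(1, d) else S <- stats::cov(data)
  }
  if (!is.matrix(query)) query <- matrix(query, ncol = d, byrow = length(query) > d)
  if (ncol(query) != d) stop("query dimension does not match the data")
  R <- tryCatch(chol(S), error = function(e)
    stop("covariance matrix is singular; jitter the data or supply S"))
  detS <- prod(diag(R))^2
  # whiten both data and queries: Mahalanobis distance = squared Euclidean
  Zd <- data %*% backsolve(R, diag(d))
  Zq <- query %*% backsolve(R, diag(d))
  const <- detS^(-1 / 2) / (n * h^d) * (2 * pi)^(-d / 2)
  out <- numeric(nrow(query))
  d2d <- rowSums(Zd^2)
  for (j in seq_len(nrow(query))) {
    u <- (d2d - 2 * drop(Zd %*% Zq[j, ]) + sum(Zq[j, ]^2)) / h^2
    out[j] <- const * sum(exp(-u / 2))
  }
  out
}

# kernel weights of each observation's regressors about x0 (shared by the
# conditional cdf and quantile estimators); constants cancel in the ratio
x_kernel_weights <- function(Z, x0, h, S = NULL) {
  if (!is.matrix(Z)) Z <- matrix(Z, ncol = 1L)
  d <- ncol(Z)
  if (is.null(S)) {
    S <- if (nrow(Z) < 2L) diag(1, d) else stats::cov(Z)
  }
  R <- tryCatch(chol(S), error = function(e)
    stop("regressor covariance is singular (constant column?); cannot form kernel weights"))
  W <- (Z - matrix(x0, nrow(Z), d, byrow = TRUE)) %*% backsolve(R, diag(d))
  exp(-rowSums(W^2) / (2 * h^2))
}

regressor_block <- function(data) {
  validate_observation_set(data)
  if (data$p < 2L) stop("conditional estimation needs at least one regressor")
  data$X[, -1L, drop = FALSE]
}

#' Kernel estimate of the conditional cdf
#'
#' Nadaraya-Watson estimator
#' \eqn{\hat{F}(y | x_0) = \sum_i K_h(x_0 - x_i) 1\{y_i \le y\} /
#' \sum_i K_h(x_0 - x_i)} with the whitened normal kernel on the
#' regressors. Monotone and right-continuous in `y`; as `h` grows it tends
#' to the marginal empirical cdf.
#'
#' @param data An `"observation_set"`.
#' @param x0 Covariate point (length `k` vector of non-intercept
#'   regressors).
#' @param y Evaluation point(s) on the response scale.
#' @param h Bandwidth on the whitened regressor scale; default
#'   [bandwidth_optimal()] with `d = k`.
#' @return Estimated conditional cdf values in `[0, 1]`.
#' @export
conditional_cdf <- function(data, x0, y, h = NULL) {
  Z <- regressor_block(data)
  if (is.null(h)) h <- bandwidth_optimal(data$n, ncol(Z))
  kw <- x_kernel_weights(Z, x0, h)
  tot <- sum(kw)
  if (!is.finite(tot) || tot <= 0)
    stop("all kernel weights are numerically zero at x0; increase the bandwidth h")
  vapply(y, function(yy) sum(kw[data$y <= yy]) / tot, numeric(1))
}

#' Kernel estimate of a conditional quantile
#'
#' Inverts the estimated conditional cdf over the observed responses:
#' \eqn{\hat{\xi}(\tau | x_0) = \inf\{y : \hat{F}(y | x_0) \ge \tau\}},
#' evaluated on the sorted sample values of `y` (the estimator is a step
#' function with jumps only there).
#'
#' @inheritParams conditional_cdf
#' @param tau Quantile level in (0, 1).
#' @return The smallest observed response at which the estimated
#'   conditional cdf reaches `tau`.
#' @export
conditional_quantile_est <- function(data, x0, tau, h = NULL) {
  check_tau(tau)
  Z <- regressor_block(data)
  if (is.null(h)) h <- bandwidth_optimal(data$n, ncol(Z))
  kw <- x_kernel_weights(Z, x0, h)
  tot <- sum(kw)
  if (!is.finite(tot) || tot <= 0)
    stop("all kernel weights are numerically zero at x0; increase the bandwidth h")
  ord <- order(data$y)
  cum <- cumsum(kw[ord]) / tot
  ys <- data$y[ord]
  idx <- which(cum >= tau - 1e-12)
  if (!length(idx)) return(ys[length(ys)])
  ys[idx[1L]]
}

#' Kernel-estimated conditional-density observation weights
#'
#' The feasible version of the conditional-density weight: for each
#' observation, estimate its conditional quantile
#' \eqn{\hat{\xi}_i = \hat{\xi}(\tau | x_i)} by conditional-cdf inversion,
#' then weight by the estimated conditional density there,
#' \eqn{\hat{w}_i = \hat{f}(\hat{\xi}_i | x_i) =
#' \hat{f}(\hat{\xi}_i, x_i) / \hat{\mu}(x_i)}, a ratio of Fukunaga kernel
#' density estimates of the joint (dimension `k + 1`) and marginal
#' (dimension `k`) laws, each with its own rule-of-thumb bandwidth and its
#' own coordinate covariance.
#'
#' @param data An `"observation_set"` with `n >= 10` and at least one
#'   non-constant regressor.
#' @param tau Quantile level in (0, 1).
#' @param h_cdf Bandwidth for the conditional-cdf inversion step; default
#'   [bandwidth_optimal()] on the regressor block.
#' @return A `"weight_vector"` with `kind = "density_kde"` and attribute
#'   `xi_hat` carrying the per-observation quantile estimates.
#' @export
density_weights <- function(data, tau, h_cdf = NULL) {
  check_tau(tau)
  Z <- regressor_block(data)
  if (data$n < 10L) stop("kernel density weights need at least 10 observations")
  if (any(apply(Z, 2L, stats::sd) == 0)) stop("regressors must not be constant")
  n <- data$n; k <- ncol(Z)
  if (is.null(h_cdf)) h_cdf <- bandwidth_optimal(n, k)
  # per-observation conditional quantile estimates (vectorized over i):
  # one n x n kernel-weight pass, then row-wise cdf inversion
  Sx <- stats::cov(Z)
  Rx <- tryCatch(chol(Sx), error = function(e)
    stop("regressor covariance is singular (constant column?); cannot form kernel weights"))
  Zw <- Z %*% backsolve(Rx, diag(k))
  d2 <- as.matrix(stats::dist(Zw))^2
  KW <- exp(-d2 / (2 * h_cdf^2))
  ord <- order(data$y)
  ys <- data$y[ord]
  xi_hat <- numeric(n)
  for (i in seq_len(n)) {
    cum <- cumsum(KW[i, ord])
    cum <- cum / cum[n]
    idx <- which(cum >= tau - 1e-12)
    xi_hat[i] <- if (length(idx)) ys[idx[1L]] else ys[n]
  }
  joint <- cbind(data$y, Z)
  f_joint <- mv_kde(joint, cbind(xi_hat, Z), h = bandwidth_optimal(n, k + 1))
  f_marg <- mv_kde(Z, Z, h = bandwidth_optimal(n, k))
  w <- f_joint / f_marg
  if (any(!is.finite(w)) || any(w <= 0))
    stop("non-positive or non-finite estimated density weight; increase the bandwidth")
  structure(weight_vector(w, "density_kde"), xi_hat = xi_hat)
}
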