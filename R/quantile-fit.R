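#' Check (pinball) loss
#'
#' The asymmetric absolute loss \eqn{\rho_\tau(u) = u(\tau - I(u < 0))}
#' whose expected-loss minimizer is the \eqn{\tau}th quantile. Residuals of
#' exactly zero are on the non-negative branch.
#'
#' @param u Numeric vector of residuals.
#' @param tau Quantile level in (0, 1).
#' @return Non-negative numeric vector, zero exactly where `u` is zero.
#' @examples
#' check_loss(c(2, -2, 0), 0.95)  # 1.9, 0.1, 0
#' @export
check_loss <- function(u, tau) {
  check_tau(tau)
  u * (tau - (u < 0))
}

check_tau <- function(tau) {
  if (!is.numeric(tau) || length(tau) != 1L || is.na(tau) || tau <= 0 || tau >= 1)
    stop("tau must be a single number strictly between 0 and 1")
  invisible(tau)
}

# Frisch-Newton primal-dual interior point for the quantile-regression LP.
#
# Primal:  min_{beta, u, v >= 0}  tau 1'u + (1-tau) 1'v   s.t.  X beta + u - v = y
# Dual:    max_a  y'a             s.t.  X'a = (1-tau) X'1,  0 <= a <= 1
#
# The multipliers of the dual equality constraints converge to beta-hat.
# Mehrotra predictor-corrector steps; the p x p normal-equation system keeps
# each iteration O(n p^2).
rq_ip <- function(X, y, tau, tol = 1e-11, maxit = 100L) {
  n <- nrow(X); p <- ncol(X)
  a <- rep(1 - tau, n)          # dual variable, interior start satisfying X'a = rhs
  s <- rep(tau, n)              # slack a + s = 1
  qrX <- qr(X)
  beta <- qr.coef(qrX, y)       # least-squares start for the equality multipliers
  beta[is.na(beta)] <- 0
  r <- drop(y - X %*% beta)
  delta <- 1e-5 * (1 + stats::mad(r))
  w <- pmax(r, 0) + delta       # dual stationarity X beta + w - z = y,
  z <- w - r                    # so w - z = r, both strictly positive
  scale_y <- 1 + sum(abs(y)) / n
  for (it in seq_len(maxit)) {
    gap <- sum(a * z) + sum(s * w)
    if (gap < tol * n * scale_y) break
    q <- 1 / (z / a + w / s)
    rr <- w - z
    Xq <- X * q
    AQA <- crossprod(X, Xq)
    ch <- tryCatch(chol(AQA), error = function(e) NULL)
    if (is.null(ch)) {
      ch <- chol(AQA + diag(1e-10 * (1 + diag(AQA)), p))
    }
    solve_nd <- function(rhs) backsolve(ch, forwardsolve(t(ch), rhs))
    # affine-scaling (predictor) direction
    db_aff <- solve_nd(crossprod(Xq, rr))
    da_aff <- q * (rr - drop(X %*% db_aff))
    dz_aff <- -z - (z / a) * da_aff
    dw_aff <- -w + (w / s) * da_aff
    aP <- step_len(c(a, s), c(da_aff, -da_aff))
    aD <- step_len(c(z, w), c(dz_aff, dw_aff))
    mu <- gap / (2 * n)
    mu_aff <- (sum((a + aP * da_aff) * (z + aD * dz_aff)) +
               sum((s - aP * da_aff) * (w + aD * dw_aff))) / (2 * n)
    mu_t <- mu * (mu_aff / mu)^3
    # corrector
    rz <- (mu_t - a * z - da_aff * dz_aff) / a
    rw <- (mu_t - s * w + da_aff * dw_aff) / s
    xi <- rz - rw
    db <- solve_nd(crossprod(Xq, xi))
    da <- q * (xi - drop(X %*% db))
    dz <- rz - (z / a) * da
    dw <- rw + (w / s) * da
    aP <- step_len(c(a, s), c(da, -da))
    aD <- step_len(c(z, w), c(dz, dw))
    a <- a + aP * da
    s <- s - aP * da
    z <- z + aD * dz
    w <- w + aD * dw
    beta <- beta + aD * db
  }
  list(beta = as.numeric(beta), iterations = it,
       converged = gap < tol * n * scale_y || gap < 1e-7 * n * scale_y)
}

step_len <- function(v, dv, f = 0.9995) {
  neg <- dv < 0
  if (!any(neg)) return(1)
  min(1, f * min(-v[neg] / dv[neg]))
}

# Polish an interior-point solution to an exact basic (vertex) solution:
# optima of the check-loss LP occur at fits interpolating p observations, so
# enumerate p-subsets among the observations with the smallest weighted
# absolute residuals and keep the best exact fit found.
polish_basic <- function(X, y, tau, w, beta, n_cand = NULL) {
  n <- nrow(X); p <- ncol(X)
  obj <- function(b) sum(w * check_loss(y - drop(X %*% b), tau))
  best <- list(beta = beta, objective = obj(beta))
  if (n < p) return(best)
  if (is.null(n_cand)) n_cand <- min(n, p + 3L)
  r <- abs(w * (y - drop(X %*% beta)))
  cand <- order(r)[seq_len(n_cand)]
  combs <- utils::combn(cand, p)
  for (j in seq_len(ncol(combs))) {
    idx <- combs[, j]
    B <- X[idx, , drop = FALSE]
    qb <- qr(B)
    if (qb$rank < p) next
    bc <- qr.coef(qb, y[idx])
    oc <- obj(bc)
    # prefer an exact vertex whenever it is at least as good (ties included),
    # so optimal fits interpolate p points and satisfy the subgradient
    # condition exactly
    if (oc <= best$objective + 1e-12 * (1 + abs(best$objective))) {
      best <- list(beta = as.numeric(bc), objective = oc)
    }
  }
  best
}

#' Fit quantile regression by weighted check-loss minimization
#'
#' Minimizes \eqn{\sum_i w_i \rho_\tau(y_i - x_i^T\beta)} over
#' \eqn{\beta \in R^p}. With uniform weights this is classical linear
#' quantile regression; positive non-uniform weights give the weighted
#' estimator. The problem is solved as a linear program: a Frisch-Newton
#' primal-dual interior-point pass on the bounded dual, followed by a
#' combinatorial polish to an exact basic solution (a fit interpolating
#' `p` observations), so the reported optimum is exact to solver tolerance.
#'
#' @param data An `"observation_set"`.
#' @param tau Quantile level in (0, 1).
#' @param weights A `"weight_vector"` (or plain positive numeric vector) of
#'   length `n`; `NULL` for uniform weights.
#' @return An object of class `"quantile_fit"`: list with `tau`,
#'   `coefficients` (length `p`), `objective` (minimized weighted check
#'   loss), `residuals`, `fitted`, `weights`, `weight_kind`, `status`
#'   (`"optimal"` or `"rank_deficient"`), `iterations`.
#' @examples
#' obs <- observation_set(c(1, 2, 10), x = c(1, 2, 3))
#' fit <- fit_quantile_regression(obs, tau = 0.5)
#' coef(fit)
#' @export
fit_quantile_regression <- function(data, tau, weights = NULL) {
  validate_observation_set(data)
  check_tau(tau)
  if (is.null(weights)) weights <- uniform_weights(data)
  w <- as.numeric(weights)
  if (length(w) != data$n) stop("weights must have one entry per observation")
  if (any(!is.finite(w)) || any(w <= 0)) stop("weights must be positive and finite")
  if (data$n < data$p) stop("need at least p observations to fit p coefficients")
  X <- data$X; y <- data$y
  status <- "optimal"
  qrX <- qr(X)
  keep <- seq_len(data$p)
  if (qrX$rank < data$p) {
    status <- "rank_deficient"
    keep <- qrX$pivot[seq_len(qrX$rank)]
  }
  Xk <- X[, keep, drop = FALSE]
  # the weighted problem is the unweighted problem on rows scaled by w_i,
  # since rho_tau(c u) = c rho_tau(u) for c > 0
  sol <- rq_ip(Xk * w, y * w, tau)
  pol <- polish_basic(Xk, y, tau, w, sol$beta)
  beta <- numeric(data$p)
  beta[keep] <- pol$beta
  names(beta) <- colnames(X)
  res <- y - drop(X %*% beta)
  structure(list(
    tau = tau,
    coefficients = beta,
    objective = sum(w * check_loss(res, tau)),
    residuals = res,
    fitted = y - res,
    weights = w,
    weight_kind = weight_kind(weights),
    status = status,
    iterations = sol$iterations
  ), class = "quantile_fit")
}

#' @export
coef.quantile_fit <- function(object, ...) object$coefficients

#' @export
print.quantile_fit <- function(x, ...) {
  cat(sprintf("Quantile regression fit, tau = %g (%s weights, %s)\n",
              x$tau, x$weight_kind, x$status))
  print(x$coefficients)
  cat("Objective (weighted check loss):", format(x$objective), "\n")
  invisible(x)
}

#' Predict from a quantile regression fit
#'
#' @param object A `"quantile_fit"`.
#' @param newdata Matrix of regressor values (without intercept), or a
#'   numeric vector for a single-regressor model; `NULL` returns fitted values.
#' @param ... Unused.
#' @return Numeric vector of conditional quantile estimates.
#' @export
predict.quantile_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  if (!is.matrix(newdata)) newdata <- matrix(newdata, ncol = length(object$coefficients) - 1L)
  drop(cbind(1, newdata) %*% object$coefficients)
}

#' Least-squares baseline fit
#'
#' Ordinary least squares on an observation set; the conditional-mean
#' baseline against which the quantile fits are compared.
#'
#' @param data An `"observation_set"` with `n > p` and full-rank design.
#' @return Named numeric coefficient vector of length `p`.
#' @examples
#' obs <- observation_set(c(0, 1, 0), x = c(0, 1, 2))
#' fit_least_squares(obs)  # intercept 1/3, slope 0
#' @export
fit_least_squares <- function(data) {
  validate_observation_set(data)
  if (data$n <= data$p) stop("need n > p for least squares")
  fit <- stats::lm.fit(data$X, data$y)
  if (any(is.na(fit$coefficients))) stop("design matrix is rank deficient")
  stats::setNames(fit$coefficients, colnames(data$X))
}
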