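# Independent oracles used across the test files. Each is deliberately
# naive (enumeration, quadrature, double loops) and shares no code with the
# implementation it checks.

# global minimum of the weighted check loss by enumerating every p-point
# interpolating fit (optima of the LP occur at such vertices)
qr_brute_force <- function(X, y, tau, w = rep(1, nrow(X))) {
  n <- nrow(X); p <- ncol(X)
  best_obj <- Inf; best_beta <- NULL
  for (idx in utils::combn(n, p, simplify = FALSE)) {
    B <- X[idx, , drop = FALSE]
    qb <- qr(B)
    if (qb$rank < p) next
    beta <- qr.coef(qb, y[idx])
    obj <- sum(w * check_loss(y - drop(X %*% beta), tau))
    if (obj < best_obj) { best_obj <- obj; best_beta <- beta }
  }
  list(objective = best_obj, beta = as.numeric(best_beta))
}

# naive double-loop Fukunaga kernel density estimate
kde_double_loop <- function(data, query, h, S = stats::cov(data)) {
  n <- nrow(data); d <- ncol(data)
  Si <- solve(S)
  out <- numeric(nrow(query))
  for (j in seq_len(nrow(query))) {
    acc <- 0
    for (i in seq_len(n)) {
      diff <- query[j, ] - data[i, ]
      u <- drop(t(diff) %*% Si %*% diff) / h^2
      acc <- acc + (2 * pi)^(-d / 2) * exp(-u / 2)
    }
    out[j] <- det(S)^(-1 / 2) / (n * h^d) * acc
  }
  out
}

# weighted check-loss subgradient condition at a fitted vertex: for each
# design column, the weighted score is dominated by the zero-residual rows
subgradient_ok <- function(data, fit, w = fit$weights, tol = 1e-7) {
  r <- fit$residuals
  tau <- fit$tau
  zero <- abs(r) <= tol * (1 + max(abs(data$y)))
  lhs <- abs(colSums(w * (tau - (r < 0)) * data$X * (!zero)))
  rhs <- colSums(matrix(w[zero] * max(tau, 1 - tau), nrow = sum(zero), ncol = data$p) *
                   abs(data$X[zero, , drop = FALSE]))
  all(lhs <= rhs + tol)
}

# shared full-scale efficiency benchmark for the acceptance tests (computed
# once, reused by the Table 3 and Table 4 checks)
.acceptance_cache <- new.env(parent = emptyenv())
acceptance_benchmark <- function() {
  if (is.null(.acceptance_cache$bench)) {
    .acceptance_cache$bench <- run_benchmark(
      m = 1000, n = 300, alpha = 3,
      tau_grid = c(0.95, 0.96, 0.97, 0.98, 0.99), N = 1000,
      estimators = c("regular", "weighted_oracle", "weighted_norm"),
      seed = 20260923L)
  }
  .acceptance_cache$bench
}
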