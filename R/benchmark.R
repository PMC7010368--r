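#' Integrated squared error between a fitted and the true quantile line
#'
#' For straight-line fits \eqn{\hat{Q}(\tau|x) = a_0 + a_1 x} against the
#' true line \eqn{Q_y(\tau|x) = b_0 + b_1 x}, evaluates
#' \eqn{\int_1^N \{\hat{Q}(\tau|x) - Q_y(\tau|x)\}^2 dx} in closed form
#' (the integrand is a quadratic polynomial). `N` is chosen so the joint
#' cdf of the simulation law is essentially 1 at `(N, N)`.
#'
#' @param fit_line Numeric `(intercept, slope)` of the fitted line, or a
#'   `"quantile_fit"` with `p = 2`.
#' @param true_line Numeric `(intercept, slope)` of the true line.
#' @param N Upper integration limit (`> 1`).
#' @return Non-negative scalar; zero iff the two lines coincide.
#' @export
integrated_sq_error <- function(fit_line, true_line, N) {
  if (inherits(fit_line, "quantile_fit")) fit_line <- coef(fit_line)
  if (length(fit_line) != 2L || length(true_line) != 2L)
    stop("the efficiency study compares straight-line fits (p = 2) only")
  if (N <= 1) stop("N must exceed the lower integration limit 1")
  c0 <- fit_line[[1L]] - true_line[[1L]]
  c1 <- fit_line[[2L]] - true_line[[2L]]
  c0^2 * (N - 1) + c0 * c1 * (N^2 - 1) + c1^2 * (N^3 - 1) / 3
}

#' Simulation mean squared error of a collection of line fits
#'
#' Monte Carlo average of [integrated_sq_error()] over replicate fits:
#' \eqn{SMSE = m^{-1} \sum_{i=1}^m \int_1^N (\hat{Q}_i - Q_y)^2 dx}.
#'
#' @param fits List of `"quantile_fit"` objects (or 2-vectors) from
#'   replicate samples.
#' @param true_line Numeric `(intercept, slope)` truth.
#' @param N Upper integration limit.
#' @return Non-negative scalar.
#' @export
smse_linear <- function(fits, true_line, N) {
  mean(vapply(fits, integrated_sq_error, numeric(1),
              true_line = true_line, N = N))
}

#' Monte Carlo efficiency benchmark of weighted quantile regression
#'
#' Repeats, for `m` independent bivariate-Pareto samples of size `n`:
#' fit the conditional-quantile line at each `tau` by every requested
#' estimator, and accumulate the integrated squared error against the
#' closed-form true line. Efficiency is reported as
#' \eqn{SEFF = SMSE(\mathrm{regular}) / SMSE(\mathrm{candidate})}; values
#' above 1 favor the candidate. All estimators see the same samples
#' (common random numbers), and each replicate has its own RNG substream
#' drawn from the master seed, so results are reproducible replicate by
#' replicate.
#'
#' @param m Number of Monte Carlo replicates.
#' @param n Sample size per replicate.
#' @param alpha Bivariate-Pareto tail index.
#' @param tau_grid Quantile levels to study.
#' @param N Upper limit of the error integral.
#' @param estimators Subset of `"regular"`, `"weighted_oracle"`,
#'   `"weighted_norm"`, `"weighted_kde"`.
#' @param seed Master seed.
#' @return A `"wqr_benchmark"`: list with matrices `smse` and `seff`
#'   (estimator by tau), `coefficients` (long data frame of all draws,
#'   for box plots), `failed` (count of skipped replicates), and the
#'   configuration.
#' @examples
#' \donttest{
#' b <- run_benchmark(m = 50, n = 100, alpha = 3, tau_grid = c(0.95, 0.97),
#'                    seed = 1)
#' b$seff
#' }
#' @export
run_benchmark <- function(m, n, alpha = 3,
                          tau_grid = c(0.95, 0.96, 0.97, 0.98, 0.99),
                          N = 1000,
                          estimators = c("regular", "weighted_oracle", "weighted_norm"),
                          seed = 1L) {
  stopifnot(m >= 1L, n > 2L, N > 1)
  estimators <- match.arg(estimators,
    c("regular", "weighted_oracle", "weighted_norm", "weighted_kde"),
    several.ok = TRUE)
  if (!"regular" %in% estimators) estimators <- c("regular", estimators)
  model <- bvpareto_model(alpha)
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, m)
  err <- array(0, dim = c(length(estimators), length(tau_grid)),
               dimnames = list(estimators, paste0("tau_", tau_grid)))
  used <- 0L
  failed <- 0L
  coef_rows <- vector("list", m)
  for (i in seq_len(m)) {
    data <- bvpareto_sample(n, model, seed = sub_seeds[i])
    rep_err <- array(NA_real_, dim = dim(err))
    rep_coef <- NULL
    ok <- TRUE
    for (jt in seq_along(tau_grid)) {
      tau <- tau_grid[jt]
      truth <- bvpareto_true_line(tau, model)
      for (je in seq_along(estimators)) {
        est <- estimators[je]
        wts <- switch(est,
          regular = NULL,
          weighted_oracle = oracle_weights(data, tau, model),
          weighted_norm = norm_weights(data, include_intercept = TRUE),
          weighted_kde = density_weights(data, tau))
        fit <- tryCatch(fit_quantile_regression(data, tau, wts),
                        error = function(e) NULL)
        if (is.null(fit)) { ok <- FALSE; break }
        rep_err[je, jt] <- integrated_sq_error(coef(fit), truth, N)
        rep_coef <- rbind(rep_coef,
          data.frame(replicate = i, estimator = est, tau = tau,
                     beta0 = coef(fit)[[1L]], beta1 = coef(fit)[[2L]]))
      }
      if (!ok) break
    }
    if (!ok) {
      failed <- failed + 1L
      warning(sprintf("replicate %d skipped: solver failure", i))
      next
    }
    err <- err + rep_err
    used <- used + 1L
    coef_rows[[i]] <- rep_coef
  }
  if (used == 0L) stop("all replicates failed")
  smse <- err / used
  seff <- sweep(1 / smse, 2L, smse["regular", ], "*")
  structure(list(
    smse = smse, seff = seff,
    coefficients = do.call(rbind, coef_rows),
    replicates_used = used, failed = failed,
    config = list(m = m, n = n, alpha = alpha, tau_grid = tau_grid,
                  N = N, estimators = estimators, seed = seed)
  ), class = "wqr_benchmark")
}

#' @export
print.wqr_benchmark <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Monte Carlo efficiency benchmark: m = %d (used %d), n = %d, alpha = %g, N = %g\n",
              cfg$m, x$replicates_used, cfg$n, cfg$alpha, cfg$N))
  cat("\nSMSE:\n"); print(signif(x$smse, 5))
  cat("\nSEFF (regular / candidate):\n"); print(round(x$seff, 4))
  invisible(x)
}

#' Relative R(tau) fit comparison
#'
#' Compares a weighted to an unweighted quantile fit on the same data by
#' \deqn{R(\tau) = 1 - V_{weighted}(\tau) / V_{regular}(\tau),}
#' where \eqn{V_{regular} = n^{-1}\sum_i \rho_\tau(y_i - x_i^T\hat\beta)}
#' uses the unweighted fit and \eqn{V_{weighted} = \sum_i w_i
#' \rho_\tau(y_i - x_i^T\hat\beta_w)} uses the weighted fit with its own
#' weights, exactly as each criterion is defined. Positive values indicate
#' the weighted criterion attains a lower value. Note \eqn{V_{weighted}}
#' carries the raw weights, so the statistic is not invariant to their
#' overall scale; `normalize = TRUE` rescales the weights to mean `1/n`
#' first, which makes the two criteria directly comparable.
#'
#' @param data The `"observation_set"` both fits were computed on.
#' @param tau Quantile level of both fits.
#' @param fit_regular Unweighted `"quantile_fit"`.
#' @param fit_weighted Weighted `"quantile_fit"`.
#' @param weights The `"weight_vector"` used by the weighted fit.
#' @param normalize If `TRUE`, rescale weights to mean `1/n` before
#'   forming \eqn{V_{weighted}}. Default `FALSE` (raw weights).
#' @return Scalar `R(tau) <= 1`.
#' @export
relative_R <- function(data, tau, fit_regular, fit_weighted, weights,
                       normalize = FALSE) {
  validate_observation_set(data)
  check_tau(tau)
  stopifnot(inherits(fit_regular, "quantile_fit"),
            inherits(fit_weighted, "quantile_fit"))
  if (!isTRUE(all.equal(fit_regular$tau, tau)) ||
      !isTRUE(all.equal(fit_weighted$tau, tau)))
    stop("both fits must be at the requested tau")
  w <- as.numeric(weights)
  if (length(w) != data$n) stop("weights must match the data")
  if (normalize) w <- w / (sum(w))
  v_reg <- sum(check_loss(data$y - drop(data$X %*% coef(fit_regular)), tau)) / data$n
  v_wtd <- sum(w * check_loss(data$y - drop(data$X %*% coef(fit_weighted)), tau))
  if (v_reg <= 1e-12 * (1 + mean(abs(data$y))))
    stop("regular-fit criterion is zero; Relative R is undefined")
  1 - v_wtd / v_reg
}
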