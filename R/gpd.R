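#' Generalized Pareto distribution (heavy-tailed case)
#'
#' Distribution function, density, quantile function and random generation
#' for the two-parameter GPD with shape \eqn{\gamma > 0} and scale
#' \eqn{\sigma > 0}:
#' \deqn{F(x) = 1 - (1 + \gamma x / \sigma)^{-1/\gamma}, \quad x > 0.}
#' Only the heavy-tailed branch \eqn{\gamma > 0} is supported: the package
#' models excesses over a high threshold for responses with Pareto-type
#' tails, where the shape governs tail heaviness.
#'
#' @param x Non-negative numeric vector of excess values.
#' @param params A `"gpd_params"` object (or anything `gpd_params()` accepts
#'   as a two-element list).
#' @return `gpd_cdf` returns probabilities in `[0, 1]`; `gpd_pdf` densities;
#'   `gpd_quantile` the quantile \eqn{(\sigma/\gamma)\{(1-\tau)^{-\gamma} - 1\}};
#'   `gpd_sample` random excesses.
#' @examples
#' p <- gpd_params(gamma = 1, sigma = 1)
#' gpd_cdf(1, p)       # 0.5
#' gpd_pdf(1, p)       # 0.25
#' gpd_quantile(0.5, p)  # 1
#' @name gpd
NULL

#' @param gamma Shape parameter, `> 0`.
#' @param sigma Scale parameter, `> 0`.
#' @rdname gpd
#' @export
gpd_params <- function(gamma, sigma) {
  if (!is.numeric(gamma) || length(gamma) != 1L || is.na(gamma) || gamma <= 0)
    stop("gamma must be a single positive number")
  if (!is.numeric(sigma) || length(sigma) != 1L || is.na(sigma) || sigma <= 0)
    stop("sigma must be a single positive number")
  structure(list(gamma = gamma, sigma = sigma), class = "gpd_params")
}

#' @export
print.gpd_params <- function(x, ...) {
  cat(sprintf("GPD(gamma = %g, sigma = %g)\n", x$gamma, x$sigma))
  invisible(x)
}

#' @rdname gpd
#' @export
gpd_cdf <- function(x, params) {
  if (any(x < 0)) stop("GPD support is x >= 0")
  1 - (1 + params$gamma * x / params$sigma)^(-1 / params$gamma)
}

#' @rdname gpd
#' @export
gpd_pdf <- function(x, params) {
  if (any(x < 0)) stop("GPD support is x >= 0")
  (1 + params$gamma * x / params$sigma)^(-1 / params$gamma - 1) / params$sigma
}

#' @param tau Probability (vector) in (0, 1).
#' @rdname gpd
#' @export
gpd_quantile <- function(tau, params) {
  if (any(tau <= 0) || any(tau >= 1)) stop("tau must lie strictly in (0, 1)")
  (params$sigma / params$gamma) * ((1 - tau)^(-params$gamma) - 1)
}

#' @param n Number of draws.
#' @rdname gpd
#' @export
gpd_sample <- function(n, params) {
  gpd_quantile(stats::runif(n), params)
}

#' Threshold excesses of a raw sample
#'
#' Peaks-over-threshold filtering: keeps observations above (or at) the
#' threshold `u` and returns them shifted to excesses `x - u`, preserving
#' the original order. Excesses of exactly zero (possible under `ge`) are
#' dropped, since the fitted GPD lives on the strictly positive half-line.
#'
#' @param x Numeric vector of raw observations.
#' @param threshold Threshold `u`.
#' @param comparison `"gt"` keeps `x > u` (default); `"ge"` keeps `x >= u`.
#' @return An `"exceedance_sample"`: list with `values` (positive
#'   excesses), `threshold`, `n_total` (length before filtering).
#' @export
threshold_excesses <- function(x, threshold, comparison = c("gt", "ge")) {
  comparison <- match.arg(comparison)
  x <- x[!is.na(x)]
  keep <- if (comparison == "gt") x > threshold else x >= threshold
  v <- x[keep] - threshold
  v <- v[v > 0]
  structure(list(values = v, threshold = threshold, n_total = length(x)),
            class = "exceedance_sample")
}

as_exceedances <- function(sample) {
  if (inherits(sample, "exceedance_sample")) return(sample$values)
  v <- as.numeric(sample)
  if (any(v <= 0)) stop("excess values must be strictly positive")
  v
}

gpd_loglik <- function(v, gamma, sigma) {
  z <- 1 + gamma * v / sigma
  if (any(z <= 0)) return(-Inf)
  -length(v) * log(sigma) - (1 / gamma + 1) * sum(log(z))
}

#' Maximum-likelihood fit of the generalized Pareto distribution
#'
#' Maximizes the GPD log-likelihood over \eqn{\gamma > 0, \sigma > 0} by
#' quasi-Newton search on \eqn{(\log\gamma, \log\sigma)}, started from
#' probability-weighted-moment estimates and from the fixed point
#' \eqn{(\gamma, \sigma) = (0.1, \bar{x})}; the best converged start wins.
#'
#' @param sample An `"exceedance_sample"` from [threshold_excesses()], or a
#'   plain vector of positive excesses. At least 10 values.
#' @return A `"gpd_fit"`: list with `params` (a `"gpd_params"`), `loglik`,
#'   `n`, `convergence` details.
#' @examples
#' set.seed(1)
#' v <- gpd_sample(500, gpd_params(0.25, 5))
#' gpd_mle(v)
#' @export
gpd_mle <- function(sample) {
  v <- as_exceedances(sample)
  n <- length(v)
  if (n < 10L) stop("need at least 10 excesses for a GPD fit")
  nll <- function(par) -gpd_loglik(v, exp(par[1L]), exp(par[2L]))
  starts <- list(c(log(0.1), log(mean(v))))
  pwm <- tryCatch({
    vs <- sort(v)
    b0 <- mean(vs)
    b1 <- sum((seq_len(n) - 1) / (n - 1) * vs) / n
    denom <- b0 - 2 * b1
    g0 <- if (denom > 0) 2 - b0 / denom else 0.5
    g0 <- min(max(g0, 0.01), 5)
    s0 <- max(b0 * (1 - g0), b0 / 2, 1e-8)
    c(log(g0), log(s0))
  }, error = function(e) NULL)
  if (!is.null(pwm)) starts <- c(starts, list(pwm))
  starts <- c(starts, list(c(log(0.5), log(stats::sd(v)))))
  best <- NULL
  for (st in starts) {
    opt <- tryCatch(
      stats::optim(st, nll, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-12)),
      error = function(e) NULL)
    if (is.null(opt) || !is.finite(opt$value)) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) stop("GPD maximum-likelihood fit failed from all starting values")
  params <- gpd_params(exp(best$par[1L]), exp(best$par[2L]))
  structure(list(params = params, loglik = -best$value, n = n,
                 convergence = best$convergence,
                 threshold = if (inherits(sample, "exceedance_sample")) sample$threshold else NA_real_),
            class = "gpd_fit")
}

#' @export
print.gpd_fit <- function(x, ...) {
  cat(sprintf("GPD maximum-likelihood fit (n = %d): gamma = %.4f, sigma = %.4f, loglik = %.3f\n",
              x$n, x$params$gamma, x$params$sigma, x$loglik))
  invisible(x)
}

# quadratic-EDF and supremum statistics against a fully specified GPD
gpd_gof_statistics <- function(v, params) {
  n <- length(v)
  u <- sort(gpd_cdf(sort(v), params))
  u <- pmin(pmax(u, 1e-12), 1 - 1e-12)
  i <- seq_len(n)
  ks <- max(i / n - u, u - (i - 1) / n)
  cvm <- 1 / (12 * n) + sum((u - (2 * i - 1) / (2 * n))^2)
  ad <- -n - mean((2 * i - 1) * (log(u) + log(1 - rev(u))))
  c(KS = ks, AD = ad, CvM = cvm)
}

#' Goodness-of-fit tests for a fitted GPD
#'
#' Kolmogorov-Smirnov (supremum), Anderson-Darling and Cramer-von Mises
#' (quadratic) statistics of the sample against the fitted GPD, with
#' p-values from a parametric bootstrap: each bootstrap replicate draws a
#' sample of the same size from the fitted GPD, *re-estimates* the
#' parameters by maximum likelihood, and recomputes the statistic, so the
#' null distribution accounts for parameter estimation.
#'
#' @param sample An `"exceedance_sample"` or vector of positive excesses
#'   (at least 10 values).
#' @param params A `"gpd_params"`; typically `gpd_mle(sample)$params`.
#' @param n_boot Number of bootstrap replicates (at least 99).
#' @param seed Optional integer seed for the bootstrap (local to this call).
#' @return Data frame with one row per test: `test`, `statistic`,
#'   `p_value`, `n_boot`.
#' @export
gpd_gof_tests <- function(sample, params, n_boot = 1000L, seed = NULL) {
  v <- as_exceedances(sample)
  if (length(v) < 10L) stop("need at least 10 excesses")
  if (stats::sd(v) == 0) stop("degenerate sample: all excesses equal")
  if (n_boot < 99L) stop("use at least 99 bootstrap replicates")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  obs <- gpd_gof_statistics(v, params)
  n <- length(v)
  exceed <- c(KS = 0L, AD = 0L, CvM = 0L)
  done <- 0L
  for (b in seq_len(n_boot)) {
    vb <- gpd_sample(n, params)
    fb <- tryCatch(gpd_mle(vb), error = function(e) NULL)
    if (is.null(fb)) next
    sb <- gpd_gof_statistics(vb, fb$params)
    exceed <- exceed + (sb >= obs)
    done <- done + 1L
  }
  p <- (1 + exceed) / (done + 1)
  data.frame(test = names(obs), statistic = as.numeric(obs),
             p_value = as.numeric(p), n_boot = done, row.names = NULL)
}
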