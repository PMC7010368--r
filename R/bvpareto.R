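#' Bivariate Pareto model
#'
#' Mardia's type-I bivariate Pareto law with joint cdf
#' \deqn{F(x, y) = 1 - x^{-\alpha} - y^{-\alpha} + (x + y - 1)^{-\alpha},
#'   \quad x > 1,\ y > 1,\ \alpha > 0,}
#' which has Pareto(\eqn{\alpha}) margins on \eqn{(1, \infty)} and *linear*
#' conditional quantile functions, making it a convenient heavy-tailed
#' ground truth for conditional-quantile estimators: the true regression
#' line is known in closed form at every quantile level.
#'
#' @param alpha Tail index \eqn{\alpha > 0}; smaller values give heavier
#'   tails. The simulation studies use \eqn{\alpha = 3}.
#' @return Object of class `"bvpareto_model"`.
#' @examples
#' m <- bvpareto_model(3)
#' bvpareto_joint_cdf(2, 2, m)
#' @export
bvpareto_model <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) || alpha <= 0)
    stop("alpha must be a single positive number")
  structure(list(alpha = alpha), class = "bvpareto_model")
}

#' @export
print.bvpareto_model <- function(x, ...) {
  cat("Bivariate Pareto model, alpha =", x$alpha, "\n")
  invisible(x)
}

#' Joint cdf of the bivariate Pareto model
#'
#' @param x,y Numeric vectors of evaluation points, both `> 1`.
#' @param model A `"bvpareto_model"`.
#' @return `F(x, y)`, in `[0, 1]`, nondecreasing in each argument, with
#'   Pareto margins `F(x, Inf) = 1 - x^-alpha`.
#' @export
bvpareto_joint_cdf <- function(x, y, model) {
  a <- model$alpha
  if (any(x <= 1) || any(y <= 1)) stop("joint cdf is defined for x > 1, y > 1")
  1 - x^(-a) - y^(-a) + (x + y - 1)^(-a)
}

#' Conditional density of y given x in the bivariate Pareto model
#'
#' \eqn{f(y | x) = (\alpha + 1) x^{\alpha + 1} (x + y - 1)^{-(\alpha + 2)}}.
#'
#' @inheritParams bvpareto_joint_cdf
#' @return Conditional density values, positive on `y > 1`.
#' @export
bvpareto_conditional_pdf <- function(y, x, model) {
  a <- model$alpha
  if (any(x < 1) || any(y < 1)) stop("conditional pdf is defined for x >= 1, y >= 1")
  (a + 1) * x^(a + 1) / (x + y - 1)^(a + 2)
}

#' True conditional quantile line of the bivariate Pareto model
#'
#' The conditional law of \eqn{y} given \eqn{x} yields a linear quantile
#' function \eqn{\xi(\tau | x) = 1 + x\{(1 - \tau)^{-1/(\alpha + 1)} - 1\}}:
#' intercept 1 for every \eqn{\tau}, slope increasing in \eqn{\tau}. With
#' \eqn{\alpha = 3} the slope is 1.1147 at \eqn{\tau = 0.95} and 1.4028 at
#' \eqn{\tau = 0.97}.
#'
#' @param tau Quantile level in (0, 1).
#' @param x Covariate values `> 1` (may be a vector).
#' @param model A `"bvpareto_model"`.
#' @return Conditional quantile value(s) `1 + x * slope`.
#' @seealso [bvpareto_true_line()] for the (intercept, slope) pair.
#' @export
bvpareto_conditional_quantile <- function(tau, x, model) {
  check_tau(tau)
  if (any(x < 1)) stop("x must be at least 1")
  line <- bvpareto_true_line(tau, model)
  unname(line[1L] + line[2L] * x)
}

#' Intercept and slope of the true conditional quantile line
#'
#' @inheritParams bvpareto_conditional_quantile
#' @return Named numeric vector `c(intercept = 1, slope = ...)` with
#'   `slope = (1 - tau)^(-1/(alpha + 1)) - 1`.
#' @examples
#' bvpareto_true_line(0.95, bvpareto_model(3))  # slope 1.1147
#' @export
bvpareto_true_line <- function(tau, model) {
  check_tau(tau)
  c(intercept = 1, slope = (1 - tau)^(-1 / (model$alpha + 1)) - 1)
}

#' Conditional density at the conditional quantile
#'
#' Evaluates \eqn{f(\xi(\tau | x) \,|\, x) =
#' (\alpha + 1)(1 - \tau)^{(\alpha + 2)/(\alpha + 1)} / x}, the quantity
#' used as the oracle observation weight: it is the local likelihood of the
#' response near its own \eqn{\tau}th conditional quantile.
#'
#' @inheritParams bvpareto_conditional_quantile
#' @return Positive density value(s), proportional to `1/x` at fixed `tau`.
#' @export
bvpareto_density_at_quantile <- function(tau, x, model) {
  check_tau(tau)
  if (any(x < 1)) stop("x must be at least 1")
  a <- model$alpha
  (a + 1) * (1 - tau)^((a + 2) / (a + 1)) / x
}

#' Sample from the bivariate Pareto model
#'
#' Inverse-cdf composition sampling: \eqn{x} from its Pareto(\eqn{\alpha})
#' margin, then \eqn{y} from the conditional law given \eqn{x}, whose cdf
#' \eqn{F(y|x) = 1 - x^{\alpha+1}(x + y - 1)^{-(\alpha+1)}} inverts to
#' \eqn{y = 1 + x\{(1 - u)^{-1/(\alpha + 1)} - 1\}}. Deterministic given
#' `seed`.
#'
#' @param n Number of pairs to draw.
#' @param model A `"bvpareto_model"`.
#' @param seed Optional integer seed (local to this call).
#' @return An `"observation_set"` with response `y` and single regressor
#'   `x`; both margins exceed 1.
#' @export
bvpareto_sample <- function(n, model, seed = NULL) {
  if (n < 1L) stop("n must be at least 1")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  a <- model$alpha
  x <- (1 - stats::runif(n))^(-1 / a)
  y <- 1 + x * ((1 - stats::runif(n))^(-1 / (a + 1)) - 1)
  observation_set(y, x, names = "x")
}

#' Oracle conditional-density weights for bivariate Pareto data
#'
#' The closed-form weight \eqn{w_i = f(\xi(\tau | x_i) \,|\, x_i)}
#' available when the data-generating law is known; for \eqn{\alpha = 3}
#' this is \eqn{4 (1 - \tau)^{5/4} / x_i}. Used as the infeasible benchmark
#' the kernel-estimated weights are compared against.
#'
#' @param data An `"observation_set"` whose single regressor is the
#'   bivariate-Pareto `x` (all values `> 1`).
#' @param tau Quantile level in (0, 1).
#' @param model A `"bvpareto_model"`.
#' @return A `"weight_vector"` with `kind = "density_oracle"`.
#' @export
oracle_weights <- function(data, tau, model) {
  validate_observation_set(data)
  if (data$p != 2L) stop("oracle weights are defined for the single-regressor model")
  x <- data$X[, 2L]
  weight_vector(bvpareto_density_at_quantile(tau, x, model), "density_oracle")
}
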