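#' Construct an observation set for quantile regression
#'
#' Bundles a response vector with a design matrix whose first column is the
#' intercept. All model-fitting functions in the package consume this
#' container.
#'
#' @param y Numeric response vector of length `n`. No missing values.
#' @param x Numeric matrix (or vector, or data frame) of regressors,
#'   `n` rows by `k` columns, *without* the intercept column; the constant
#'   column is prepended here. Pass `NULL` for an intercept-only model.
#' @param names Optional character vector of regressor names (length `k`).
#'
#' @return An object of class `"observation_set"`: a list with elements
#'   `y` (length-`n` response), `X` (`n` by `p` design with leading
#'   intercept column, `p = k + 1`), `n`, `p`.
#'
#' @examples
#' obs <- observation_set(y = c(1, 2, 10), x = c(1, 2, 3))
#' obs$X
#' @export
observation_set <- function(y, x = NULL, names = NULL) {
  y <- as.numeric(y)
  n <- length(y)
  if (n < 1L) stop("need at least one observation")
  if (anyNA(y) || any(!is.finite(y))) stop("response contains missing or non-finite values")
  if (is.null(x)) {
    X <- matrix(1, n, 1)
    colnames(X) <- "(Intercept)"
  } else {
    if (is.data.frame(x)) x <- as.matrix(x)
    if (!is.matrix(x)) x <- matrix(as.numeric(x), ncol = 1L)
    storage.mode(x) <- "double"
    if (nrow(x) != n) stop("x must have as many rows as y has elements")
    if (anyNA(x) || any(!is.finite(x))) stop("regressors contain missing or non-finite values")
    if (!is.null(names)) colnames(x) <- names
    if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
    X <- cbind("(Intercept)" = 1, x)
  }
  structure(list(y = y, X = X, n = n, p = ncol(X)), class = "observation_set")
}

#' Coerce to an observation set
#'
#' @param object Object to coerce. Supported: `"observation_set"` (returned
#'   unchanged) and data frames, in which case `response` and `covariates`
#'   name the columns to use.
#' @param response Name of the response column (data-frame method).
#' @param covariates Character vector of regressor column names.
#' @param ... Unused.
#' @return An `"observation_set"`.
#' @export
as_observation_set <- function(object, ...) UseMethod("as_observation_set")

#' @rdname as_observation_set
#' @export
as_observation_set.observation_set <- function(object, ...) object

#' @rdname as_observation_set
#' @export
as_observation_set.data.frame <- function(object, response, covariates = NULL, ...) {
  missing_cols <- setdiff(c(response, covariates), names(object))
  if (length(missing_cols))
    stop("column(s) not found: ", paste(missing_cols, collapse = ", "))
  x <- if (length(covariates)) as.matrix(object[covariates]) else NULL
  observation_set(object[[response]], x, names = covariates)
}

#' @export
print.observation_set <- function(x, ...) {
  cat("Observation set: n =", x$n, ", p =", x$p,
      "(", paste(colnames(x$X), collapse = ", "), ")\n")
  invisible(x)
}

validate_observation_set <- function(data) {
  if (!inherits(data, "observation_set")) stop("expected an observation_set")
  stopifnot(length(data$y) == nrow(data$X), ncol(data$X) == data$p)
  if (any(data$X[, 1L] != 1)) stop("first design column must be the intercept")
  invisible(data)
}

#' Construct a per-observation weight vector
#'
#' @param w Positive, finite numeric weights, one per observation.
#' @param kind Provenance of the weights: `"uniform"`, `"norm"`
#'   (inverse-regressor-norm, normalized to sum 1), `"density_oracle"`
#'   (closed-form conditional density at the true quantile) or
#'   `"density_kde"` (kernel-estimated conditional density).
#' @return Numeric vector of class `"weight_vector"` with attribute `kind`.
#' @export
weight_vector <- function(w, kind = c("uniform", "norm", "density_oracle", "density_kde")) {
  kind <- match.arg(kind)
  w <- as.numeric(w)
  if (any(!is.finite(w)) || any(w <= 0)) stop("weights must be positive and finite")
  if (kind == "norm" && abs(sum(w) - 1) > 1e-8)
    stop("norm weights must sum to 1")
  structure(w, kind = kind, class = "weight_vector")
}

#' @export
print.weight_vector <- function(x, ...) {
  cat("Weight vector (", attr(x, "kind"), "), n = ", length(x), "\n", sep = "")
  print(utils::head(as.numeric(x)))
  invisible(x)
}

weight_kind <- function(w) {
  k <- attr(w, "kind")
  if (is.null(k)) "uniform" else k
}

#' Uniform weights for an observation set
#'
#' @param data An `"observation_set"`.
#' @return A `"weight_vector"` of ones, `kind = "uniform"`.
#' @export
uniform_weights <- function(data) {
  validate_observation_set(data)
  weight_vector(rep(1, data$n), "uniform")
}

#' Inverse-norm observation weights
#'
#' Weights each observation by the reciprocal Euclidean norm of its
#' non-intercept regressors, normalized so the weights sum to one:
#' \eqn{w_i = \|x_i\|^{-1} / \sum_j \|x_j\|^{-1}} with
#' \eqn{\|x_i\|^2 = x_{i1}^2 + \cdots + x_{ik}^2}. The intercept column is
#' excluded from the norm. Observations far from the origin in regressor
#' space are down-weighted.
#'
#' @param data An `"observation_set"` with at least one non-intercept
#'   regressor; every regressor row must have nonzero norm.
#' @param include_intercept If `TRUE`, the norm is taken over the full
#'   design row including the constant coordinate,
#'   \eqn{\|x_i\| = \sqrt{1 + x_{i1}^2 + \cdots + x_{ik}^2}}. Default
#'   `FALSE` (regressors only). For a single-regressor model on a
#'   positive covariate the regressor-only weights are exactly
#'   proportional to \eqn{1/x_i} — the same direction as the
#'   conditional-density oracle weights of the bivariate-Pareto model, to
#'   which check-loss fits are then identical (weight scale does not
#'   affect the minimizer); include the intercept when a genuinely
#'   different comparison estimator is wanted.
#' @return A `"weight_vector"` with `kind = "norm"`, summing to one.
#' @examples
#' obs <- observation_set(c(1, 2), x = c(1, 3))
#' norm_weights(obs)  # 0.75, 0.25
#' @export
norm_weights <- function(data, include_intercept = FALSE) {
  validate_observation_set(data)
  if (data$p < 2L) stop("norm weights need at least one non-intercept regressor")
  Z <- if (include_intercept) data$X else data$X[, -1L, drop = FALSE]
  nrm <- sqrt(rowSums(Z^2))
  zero <- which(nrm == 0)
  if (length(zero))
    stop("zero-norm regressor row(s): ", paste(zero, collapse = ", "))
  w <- (1 / nrm) / sum(1 / nrm)
  weight_vector(w, "norm")
}
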