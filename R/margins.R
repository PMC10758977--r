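# Binomial-logistic marginal model: linear predictor, success probability,
# pmf/cdf/quantile with the F(-1) = 0 convention the rectangle probability
# needs at zero counts. pmf/cdf/quantile delegate to stats::dbinom/pbinom/
# qbinom (log-space / regularized incomplete beta internally), wrapped with
# the validation and conventions of this model.

#' Binomial-logistic margin model
#'
#' Holds the regression coefficient vector \eqn{\beta = (\beta_0, \beta_1,
#' \dots, \beta_d)} of the logit-linear success probability
#' \eqn{\mathrm{logit}(\pi_t) = X_t \beta}.
#'
#' @param beta Numeric vector of finite coefficients (intercept first).
#' @return An object of class `"margin_model"`.
#' @export
margin_model <- function(beta) {
  if (!is.numeric(beta) || length(beta) < 1L || any(!is.finite(beta)))
    stop("`beta` must be a numeric vector of finite coefficients")
  structure(list(beta = as.numeric(beta)), class = "margin_model")
}

#' Binomial time series container
#'
#' Aligned observations \eqn{(y_t, n_t, X_t)} for \eqn{t = 1, \dots, T}:
#' success counts, trial counts and a design matrix whose first column is
#' the intercept.
#'
#' @param y Integer vector of success counts.
#' @param n Integer vector of trial counts (`n >= 1`).
#' @param X Design matrix `T x (d+1)` with a leading column of ones, or a
#'   `T x d` covariate matrix to which the intercept column is prepended.
#' @return An object of class `"binomial_series"` with fields `y`, `n`, `X`,
#'   `T` (length) and `d` (number of covariates).
#' @export
binomial_series <- function(y, n, X) {
  if (anyNA(y) || anyNA(n)) stop("`y` and `n` must not contain missing values")
  if (any(y != floor(y)) || any(n != floor(n)))
    stop("`y` and `n` must be integer-valued")
  if (any(n < 1)) stop("all trial counts n must be >= 1")
  if (any(y < 0 | y > n)) {
    bad <- which(y < 0 | y > n)[1]
    stop(sprintf("y exceeds n at row %d (y=%d, n=%d)", bad, y[bad], n[bad]))
  }
  Tn <- length(y)
  if (length(n) != Tn) stop("`y` and `n` must have equal length")
  if (Tn < 2) stop("a binomial series needs at least T = 2 time points")
  X <- as.matrix(X)
  if (!is.numeric(X) || anyNA(X)) stop("`X` must be numeric without missing values")
  if (nrow(X) != Tn) stop("`X` must have one row per time point")
  if (!all(X[, 1] == 1)) X <- cbind(1, X)
  cn <- colnames(X)
  if (is.null(cn) || !all(nzchar(cn)))
    cn <- c("(Intercept)",
            if (ncol(X) > 1L) paste0("x", seq_len(ncol(X) - 1L)))
  cn[1] <- "(Intercept)"
  colnames(X) <- cn
  structure(list(y = as.integer(y), n = as.integer(n), X = X,
                 T = Tn, d = ncol(X) - 1L),
            class = "binomial_series")
}

#' @export
print.binomial_series <- function(x, ...) {
  cat(sprintf("binomial_series: T = %d time points, %d covariate(s), n in [%d, %d]\n",
              x$T, x$d, min(x$n), max(x$n)))
  invisible(x)
}

#' Success probability from the logit-linear model
#'
#' \eqn{\pi = \exp(X\beta) / (1 + \exp(X\beta))}, computed stably for
#' extreme linear predictors (no underflow to exactly 0 or 1 for
#' \eqn{|X\beta|} up to ~700).
#'
#' @param margin A [margin_model()].
#' @param X_row Covariate vector (with leading 1) or a design matrix.
#' @return Success probabilities in \eqn{(0, 1)}.
#' @export
success_prob <- function(margin, X_row) {
  if (!inherits(margin, "margin_model")) stop("`margin` must be a margin_model")
  X <- if (is.matrix(X_row)) X_row else matrix(X_row, nrow = 1)
  if (ncol(X) != length(margin$beta))
    stop(sprintf("dimension mismatch: %d columns vs %d coefficients",
                 ncol(X), length(margin$beta)))
  stats::plogis(drop(X %*% margin$beta))
}

#' Binomial probability mass function
#'
#' @param y Counts, `0 <= y <= n`.
#' @param n Trial counts.
#' @param pi Success probabilities.
#' @param log Return log probabilities?
#' @return Probability mass (or its log).
#' @export
binom_pmf <- function(y, n, pi, log = FALSE) {
  if (any(y < 0 | y > n)) stop("y must lie in [0, n]")
  stats::dbinom(y, n, pi, log = log)
}

#' Binomial distribution function with F(-1) = 0
#'
#' \eqn{F(y) = \sum_{k=0}^{y} f(k)}; `y < 0` returns 0 (the empty-sum
#' convention the rectangle probability requires at zero counts) and
#' `y >= n` returns 1.
#'
#' @inheritParams binom_pmf
#' @return Cumulative probabilities in \eqn{[0, 1]}.
#' @export
binom_cdf <- function(y, n, pi) {
  if (any(n < 1)) stop("n must be >= 1")
  stats::pbinom(floor(y), n, pi)
}

#' Binomial quantile (generalized inverse CDF)
#'
#' Smallest `y` with `F(y) >= p`.
#'
#' @param p Probabilities strictly inside \eqn{(0, 1)}.
#' @inheritParams binom_pmf
#' @return Integer counts in `[0, n]`.
#' @export
binom_ppf <- function(p, n, pi) {
  if (any(p <= 0 | p >= 1)) stop("p must lie strictly inside (0, 1)")
  stats::qbinom(p, n, pi)
}
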