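# Copula-based Markov chain likelihood for binomial-logistic margins:
# PIT bounds, rectangle (joint) and transition probabilities, the full
# log-likelihood, joint MLE of (beta, alpha) with observed-information
# standard errors, one-step prediction, and fit metrics.
#
# The joint pmf of an adjacent pair is the copula volume over the CDF-jump
# rectangle:
#   Pr(Y_t = y_t, Y_{t-1} = y_{t-1})
#     = C(u_t, v_t) - C(u_t, v_t^-) - C(u_t^-, v_t) + C(u_t^-, v_t^-)
# with u_t = F(y_t | X_t), u_t^- = F(y_t - 1 | X_t) and likewise for v at
# t - 1. The full likelihood is the exact Markov chain-rule expansion:
#   L = log f_1(y_1) + sum_{t=2}^T [ log DeltaC_t - log f_{t-1}(y_{t-1}) ].

# rectangle probabilities below this are floored before logging
.rect_floor <- 1e-300
# in the likelihood the floor is relative: DeltaC_t is clamped below at
# .rect_rel_floor * f_t * f_{t-1} (a transition this much less likely than
# under independence is numerically indistinguishable from impossible).
# An absolute floor would let the -log f_{t-1} term dominate and fabricate
# an ascent direction for the optimizer.
.rect_rel_floor <- 1e-10

# construct a spec without constructor validation (optimizer-internal;
# the transform keeps alpha inside the family domain)
.spec_unchecked <- function(family, alpha) {
  structure(list(family = family, alpha = alpha), class = "copula_spec")
}

#' Probability-integral-transform bounds for one transition
#'
#' For discrete margins the PIT of an observation is the interval
#' \eqn{[F(y-1), F(y)]}. This returns the four corner coordinates of the
#' rectangle for transition `t`: `u = F(y_t | X_t)`, `u_minus = F(y_t - 1 |
#' X_t)`, `v = F(y_{t-1} | X_{t-1})`, `v_minus = F(y_{t-1} - 1 | X_{t-1})`.
#'
#' @param margin A [margin_model()].
#' @param series A [binomial_series()].
#' @param t Time index, `2 <= t <= T`.
#' @return A list with fields `u`, `v`, `u_minus`, `v_minus`.
#' @export
pit_bounds <- function(margin, series, t) {
  if (!inherits(series, "binomial_series")) stop("`series` must be a binomial_series")
  if (length(t) != 1L || t < 2 || t > series$T) stop("`t` must satisfy 2 <= t <= T")
  pi_t  <- success_prob(margin, series$X[t, , drop = FALSE])
  pi_tm <- success_prob(margin, series$X[t - 1, , drop = FALSE])
  list(u       = binom_cdf(series$y[t],      series$n[t],      pi_t),
       v       = binom_cdf(series$y[t - 1],  series$n[t - 1],  pi_tm),
       u_minus = binom_cdf(series$y[t] - 1,  series$n[t],      pi_t),
       v_minus = binom_cdf(series$y[t - 1] - 1, series$n[t - 1], pi_tm))
}

#' Rectangle probability of an adjacent pair
#'
#' The copula volume over the PIT rectangle, i.e. the joint pmf
#' \eqn{\Pr(Y_t = y_t, Y_{t-1} = y_{t-1})}.
#'
#' @param spec A [copula_spec()].
#' @param b PIT bounds from [pit_bounds()] (fields `u`, `v`, `u_minus`,
#'   `v_minus`; each may be a vector).
#' @return Nonnegative probabilities.
#' @export
rectangle_prob <- function(spec, b) {
  dc <- copula_cdf(spec, b$u, b$v) - copula_cdf(spec, b$u, b$v_minus) -
        copula_cdf(spec, b$u_minus, b$v) + copula_cdf(spec, b$u_minus, b$v_minus)
  pmax(dc, 0)
}

#' Transition probability mass function
#'
#' \eqn{\Pr(Y_t = y \mid Y_{t-1} = y_{t-1})} for candidate values `y`,
#' i.e. the rectangle probability divided by the marginal pmf of the
#' conditioning observation.
#'
#' @inheritParams pit_bounds
#' @param spec A [copula_spec()].
#' @param y_candidate Integer vector of candidate counts in `[0, n_t]`.
#' @return Probabilities summing to 1 over `y_candidate = 0..n_t`.
#' @export
transition_pmf <- function(spec, margin, series, t, y_candidate) {
  if (any(y_candidate < 0 | y_candidate > series$n[t]))
    stop("`y_candidate` must lie in [0, n_t]")
  pi_t  <- success_prob(margin, series$X[t, , drop = FALSE])
  pi_tm <- success_prob(margin, series$X[t - 1, , drop = FALSE])
  f_prev <- binom_pmf(series$y[t - 1], series$n[t - 1], pi_tm)
  if (f_prev < .rect_floor)
    stop(sprintf("conditioning pmf is numerically zero at t = %d", t))
  v  <- binom_cdf(series$y[t - 1],     series$n[t - 1], pi_tm)
  vm <- binom_cdf(series$y[t - 1] - 1, series$n[t - 1], pi_tm)
  u  <- binom_cdf(y_candidate,     series$n[t], pi_t)
  um <- binom_cdf(y_candidate - 1, series$n[t], pi_t)
  rectangle_prob(spec, list(u = u, v = v, u_minus = um, v_minus = vm)) / f_prev
}

# Vectorised log-likelihood core. Returns the log-likelihood with an
# attribute n_floored counting rectangle probabilities clamped at the
# floor (each contributes log(.rect_floor) ~ -690.8).
.loglik_core <- function(family, alpha, beta, series, include_first = TRUE) {
  spec <- .spec_unchecked(family, alpha)
  eta <- drop(series$X %*% beta)
  pi <- stats::plogis(eta)
  Tn <- series$T
  u  <- stats::pbinom(series$y, series$n, pi)
  um <- stats::pbinom(series$y - 1L, series$n, pi)
  logf <- stats::dbinom(series$y, series$n, pi, log = TRUE)
  b <- list(u = u[2:Tn], v = u[1:(Tn - 1)],
            u_minus = um[2:Tn], v_minus = um[1:(Tn - 1)])
  dc <- rectangle_prob(spec, b)
  ldc <- log(dc)
  lower <- log(.rect_rel_floor) + logf[2:Tn] + logf[1:(Tn - 1)]
  n_floored <- sum(ldc < lower)
  ll <- sum(pmax(ldc, lower)) - sum(logf[1:(Tn - 1)])
  if (include_first) ll <- ll + logf[1]
  structure(ll, n_floored = n_floored)
}

#' Log-likelihood of the copula-based Markov chain model
#'
#' \eqn{L(\beta, \alpha) = \log f_1(y_1) + \sum_{t=2}^{T} [\log \Delta C_t -
#' \log f_{t-1}(y_{t-1})]}, the exact chain-rule expansion of the joint pmf
#' of the chain. `include_first = FALSE` drops the marginal term of the
#' first observation (the conditional likelihood).
#'
#' @param spec A [copula_spec()].
#' @param margin A [margin_model()].
#' @param series A [binomial_series()].
#' @param include_first Include \eqn{\log f_1(y_1)}? Default `TRUE`.
#' @return The log-likelihood, with attribute `n_floored` counting
#'   rectangle probabilities clamped at the relative floor
#'   `1e-10 * f_t * f_{t-1}` before logging (a warning is raised when any
#'   are).
#' @export
cmc_loglik <- function(spec, margin, series, include_first = TRUE) {
  .check_spec(spec)
  if (!inherits(margin, "margin_model")) stop("`margin` must be a margin_model")
  if (!inherits(series, "binomial_series")) stop("`series` must be a binomial_series")
  if (any(!is.finite(margin$beta))) stop("non-finite parameters")
  ll <- .loglik_core(spec$family, spec$alpha, margin$beta, series, include_first)
  if (attr(ll, "n_floored") > 0)
    warning(sprintf("%d rectangle probabilities underflowed and were floored",
                    attr(ll, "n_floored")))
  ll
}

#' Numerical score (gradient) of the log-likelihood
#'
#' Central finite differences of [cmc_loglik()] in \eqn{(\beta, \alpha)},
#' the gradient actually used by the optimizer. The analytic score has the
#' structure \eqn{\partial L/\partial \alpha = \sum_t \Delta C_{t,\alpha}' /
#' \Delta C_t}; this numerical version is the package's authoritative
#' gradient (see the methods vignette).
#'
#' @inheritParams cmc_loglik
#' @param eps Relative step for the central differences.
#' @return Gradient vector, ordered `(beta_0, ..., beta_d, alpha)`.
#' @export
cmc_score <- function(spec, margin, series, include_first = TRUE, eps = 1e-6) {
  .check_spec(spec)
  theta <- c(margin$beta, spec$alpha)
  f <- function(th) {
    as.numeric(.loglik_core(spec$family, th[length(th)],
                            th[-length(th)], series, include_first))
  }
  vapply(seq_along(theta), function(j) {
    h <- eps * max(1, abs(theta[j]))
    tp <- theta; tp[j] <- tp[j] + h
    tm <- theta; tm[j] <- tm[j] - h
    (f(tp) - f(tm)) / (2 * h)
  }, numeric(1))
}

# unconstrained <-> natural parameterization of alpha per family
.alpha_to_psi <- function(family, alpha) {
  switch(family, clayton = log(alpha), gumbel = log(alpha - 1), frank = alpha)
}
.psi_to_alpha <- function(family, psi) {
  switch(family, clayton = exp(psi), gumbel = 1 + exp(psi), frank = psi)
}
.dalpha_dpsi <- function(family, psi) {
  switch(family, clayton = exp(psi), gumbel = exp(psi), frank = 1)
}

# central-difference Hessian (no numDeriv dependency)
.num_hessian <- function(f, x, eps = 1e-4) {
  p <- length(x)
  h <- eps * pmax(1, abs(x))
  H <- matrix(NA_real_, p, p)
  f0 <- f(x)
  for (i in seq_len(p)) {
    for (j in i:p) {
      if (i == j) {
        xp <- x; xp[i] <- x[i] + h[i]
        xm <- x; xm[i] <- x[i] - h[i]
        H[i, i] <- (f(xp) - 2 * f0 + f(xm)) / h[i]^2
      } else {
        xpp <- x; xpp[c(i, j)] <- x[c(i, j)] + h[c(i, j)]
        xpm <- x; xpm[i] <- x[i] + h[i]; xpm[j] <- x[j] - h[j]
        xmp <- x; xmp[i] <- x[i] - h[i]; xmp[j] <- x[j] + h[j]
        xmm <- x; xmm[c(i, j)] <- x[c(i, j)] - h[c(i, j)]
        H[i, j] <- H[j, i] <- (f(xpp) - f(xpm) - f(xmp) + f(xmm)) /
          (4 * h[i] * h[j])
      }
    }
  }
  H
}

#' Fit the copula-based Markov chain logistic regression model
#'
#' Simultaneous maximum-likelihood estimation of the regression
#' coefficients and the copula dependence parameter by quasi-Newton (BFGS)
#' iterations on \eqn{(\beta, \psi)}, where \eqn{\psi} is an unconstrained
#' reparameterization of \eqn{\alpha} (Clayton: \eqn{\log\alpha}; Gumbel:
#' \eqn{\log(\alpha - 1)}; Frank: identity). Standard errors come from the
#' inverse observed information (central-difference Hessian at the optimum),
#' delta-method-transformed back to the natural \eqn{\alpha} scale.
#'
#' @param series A [binomial_series()].
#' @param family Copula family: `"clayton"`, `"gumbel"` or `"frank"`.
#' @param include_first Include the first observation's marginal term in
#'   the likelihood (default `TRUE`).
#' @param start `"glm"` (default) initializes \eqn{\beta} from an
#'   independent binomial-logistic fit; `"zero"` starts from all zeros
#'   (kept for fidelity with the historical algorithm; it stalls on data
#'   with large linear predictors). A numeric vector of length `d + 1`
#'   supplies explicit starting coefficients.
#' @param alpha0 Starting dependence parameter; default
#'   `tau_to_param(family, 0.2)`.
#' @param control Passed to [stats::optim()] (defaults: `maxit = 500`,
#'   `reltol = 1e-10`).
#' @return A `"cmc_fit"` object: `beta_hat`, `alpha_hat`, `se` (ordered
#'   `beta0..betad, alpha`; `NA` when the Hessian is not positive definite),
#'   `loglik`, `converged`, `n_iter`, `family`, plus `tau_hat` and
#'   `n_floored`.
#' @export
cmc_fit <- function(series, family = c("clayton", "gumbel", "frank"),
                    include_first = TRUE, start = c("glm", "zero"),
                    alpha0 = NULL, control = list()) {
  family <- match.arg(family)
  if (!inherits(series, "binomial_series")) stop("`series` must be a binomial_series")
  if (all(series$y == 0L) || all(series$y == series$n))
    stop("degenerate series: all counts at the same boundary; beta is unidentifiable")
  p <- ncol(series$X)
  beta0 <- if (is.numeric(start)) {
    if (length(start) != p) stop("numeric `start` must have length d + 1")
    start
  } else if (match.arg(start) == "glm") {
    g <- stats::glm.fit(series$X, cbind(series$y, series$n - series$y),
                        family = stats::binomial())
    g$coefficients
  } else rep(0, p)
  if (is.null(alpha0)) alpha0 <- tau_to_param(family, 0.2)
  par0 <- c(beta0, .alpha_to_psi(family, alpha0))
  ctrl <- utils::modifyList(list(maxit = 500L, reltol = 1e-10), control)

  negll <- function(par) {
    ll <- .loglik_core(family, .psi_to_alpha(family, par[p + 1]),
                       par[seq_len(p)], series, include_first)
    if (!is.finite(ll)) 1e10 else -as.numeric(ll)
  }
  # explicit central-difference gradient (relative step 1e-6); optim's
  # default ndeps = 1e-3 is too coarse and stalls BFGS well short of the
  # first-order condition
  grad <- function(par) {
    vapply(seq_along(par), function(j) {
      h <- 1e-6 * max(1, abs(par[j]))
      pp <- par; pp[j] <- pp[j] + h
      pm <- par; pm[j] <- pm[j] - h
      (negll(pp) - negll(pm)) / (2 * h)
    }, numeric(1))
  }
  opt <- stats::optim(par0, negll, gr = grad, method = "BFGS", control = ctrl)

  alpha_hat <- unname(.psi_to_alpha(family, opt$par[p + 1]))
  beta_hat <- opt$par[seq_len(p)]
  names(beta_hat) <- colnames(series$X)

  se <- rep(NA_real_, p + 1)
  H <- tryCatch(.num_hessian(negll, opt$par), error = function(e) NULL)
  if (!is.null(H) && all(is.finite(H))) {
    cov_psi <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(cov_psi) && all(diag(cov_psi) > 0)) {
      J <- diag(p + 1)
      J[p + 1, p + 1] <- .dalpha_dpsi(family, opt$par[p + 1])
      se <- sqrt(diag(J %*% cov_psi %*% t(J)))
    }
  }
  if (anyNA(se))
    warning("observed information not positive definite; standard errors reported as NA")
  names(se) <- c(names(beta_hat), "alpha")

  ll_final <- .loglik_core(family, alpha_hat, beta_hat, series, include_first)
  structure(list(
    beta_hat = beta_hat,
    alpha_hat = alpha_hat,
    se = se,
    loglik = as.numeric(ll_final),
    converged = opt$convergence == 0L,
    n_iter = unname(opt$counts[1]),
    family = family,
    include_first = include_first,
    tau_hat = param_to_tau(.spec_unchecked(family, alpha_hat)),
    n_floored = attr(ll_final, "n_floored")
  ), class = "cmc_fit")
}

#' @export
print.cmc_fit <- function(x, ...) {
  cat(sprintf("Copula-based Markov chain logistic regression (%s copula)\n", x$family))
  est <- c(x$beta_hat, alpha = x$alpha_hat)
  out <- data.frame(estimate = est, se = x$se)
  print(round(out, 5))
  cat(sprintf("log-likelihood: %.4f  (Kendall tau = %.4f, %s, %d iterations)\n",
              x$loglik, x$tau_hat,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  invisible(x)
}

#' One-step-ahead fitted values
#'
#' \eqn{\hat y_t = \sum_{y=0}^{n_t} y \cdot \Pr(Y_t = y \mid Y_{t-1} =
#' y_{t-1})} for \eqn{t \ge 2}; \eqn{\hat y_1 = n_1 \hat\pi_1}.
#'
#' @param object A converged [cmc_fit()].
#' @param series The [binomial_series()] to predict (typically the one the
#'   model was fitted to).
#' @param ... Unused.
#' @return Numeric vector of fitted counts, each in \eqn{[0, n_t]}.
#' @export
predict.cmc_fit <- function(object, series, ...) {
  if (!inherits(series, "binomial_series")) stop("`series` must be a binomial_series")
  spec <- copula_spec(object$family, object$alpha_hat)
  margin <- margin_model(object$beta_hat)
  pi <- success_prob(margin, series$X)
  yhat <- numeric(series$T)
  yhat[1] <- series$n[1] * pi[1]
  for (t in 2:series$T) {
    ys <- 0:series$n[t]
    yhat[t] <- sum(ys * transition_pmf(spec, margin, series, t, ys))
  }
  yhat
}

#' Fit metrics: MSE and MAPE
#'
#' `mse = mean((y - y_hat)^2)`; `mape = mean(|y - y_hat| / y)` over time
#' points with `y > 0` (zero counts are excluded from MAPE).
#'
#' @param y Observed counts.
#' @param y_hat Fitted values of equal length.
#' @return A list with components `mse` and `mape`.
#' @export
fit_metrics <- function(y, y_hat) {
  if (length(y) != length(y_hat)) stop("`y` and `y_hat` must have equal length")
  pos <- y > 0
  if (!any(pos)) stop("MAPE undefined: all observed counts are zero")
  list(mse = mean((y - y_hat)^2),
       mape = mean(abs(y[pos] - y_hat[pos]) / y[pos]))
}
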