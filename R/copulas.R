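# Bivariate Archimedean copula machinery (Clayton, Gumbel, Frank):
# CDF, density, conditional h-function and its inverse, Kendall-tau
# conversions, tail dependence. All evaluators are vectorised over (u, v).

# |alpha| below this is treated as the product (independence) copula for
# Clayton and Frank; Gumbel uses alpha - 1 against the same threshold.
# Removes 0/0 forms and lets the Markov likelihood degenerate cleanly to
# the independent binomial-logistic model.
.indep_eps <- 1e-6

#' Specify a bivariate Archimedean copula
#'
#' Constructs a validated copula specification used by all copula evaluators
#' and by the Markov chain likelihood.
#'
#' @param family One of `"clayton"`, `"gumbel"`, `"frank"`.
#' @param alpha Dependence parameter. Valid domains: Clayton `alpha > 0`
#'   (the positive-dependence branch), Gumbel `alpha >= 1`, Frank
#'   `alpha != 0`. Values within `1e-6` of the independence member
#'   (`alpha = 0` for Clayton/Frank, `alpha = 1` for Gumbel) are evaluated
#'   as the product copula.
#'
#' @return An object of class `"copula_spec"` with fields `family` and
#'   `alpha`.
#' @examples
#' sp <- copula_spec("clayton", 2)
#' copula_cdf(sp, 0.5, 0.5)
#' @export
copula_spec <- function(family = c("clayton", "gumbel", "frank"), alpha) {
  family <- match.arg(family)
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha))
    stop("`alpha` must be a single finite numeric value")
  switch(family,
    clayton = if (alpha <= 0)
      stop("Clayton copula requires alpha > 0 (positive-dependence branch)"),
    gumbel = if (alpha < 1)
      stop("Gumbel copula requires alpha >= 1"),
    frank = if (alpha == 0)
      stop("Frank copula requires alpha != 0; use alpha near 0 (< 1e-6) for the independence limit")
  )
  structure(list(family = family, alpha = as.numeric(alpha)),
            class = "copula_spec")
}

#' @export
print.copula_spec <- function(x, ...) {
  cat(sprintf("%s copula, alpha = %g (Kendall tau = %.4f)\n",
              x$family, x$alpha, param_to_tau(x)))
  invisible(x)
}

.is_copula_spec <- function(spec) inherits(spec, "copula_spec")

.check_spec <- function(spec) {
  if (!.is_copula_spec(spec))
    stop("`spec` must be a copula_spec object")
  invisible(spec)
}

.is_indep <- function(spec) {
  switch(spec$family,
    clayton = abs(spec$alpha) < .indep_eps,
    frank   = abs(spec$alpha) < .indep_eps,
    gumbel  = (spec$alpha - 1) < .indep_eps
  )
}

.check_unit <- function(x, name, open = FALSE) {
  if (!is.numeric(x) || anyNA(x))
    stop(sprintf("`%s` must be numeric without missing values", name))
  if (open) {
    if (any(x <= 0 | x >= 1))
      stop(sprintf("`%s` must lie strictly inside (0, 1)", name))
  } else if (any(x < 0 | x > 1)) {
    stop(sprintf("`%s` must lie in [0, 1]", name))
  }
  invisible(x)
}

#' Copula distribution function
#'
#' Evaluates the bivariate copula CDF \eqn{C(u, v; \alpha)}.
#' Boundary identities are exact: \eqn{C(u,0)=C(0,v)=0}, \eqn{C(u,1)=u},
#' \eqn{C(1,v)=v}.
#'
#' @param spec A [copula_spec()].
#' @param u,v Numeric vectors in \eqn{[0, 1]} (recycled to common length).
#' @return Numeric vector of copula values in \eqn{[0, 1]}.
#' @export
copula_cdf <- function(spec, u, v) {
  .check_spec(spec)
  .check_unit(u, "u"); .check_unit(v, "v")
  k <- max(length(u), length(v))
  u <- rep_len(u, k); v <- rep_len(v, k)
  if (.is_indep(spec)) return(u * v)
  a <- spec$alpha
  out <- switch(spec$family,
    clayton = {
      r <- u^(-a) + v^(-a) - 1
      r^(-1 / a)
    },
    gumbel = {
      x <- -log(u); y <- -log(v)
      m <- pmax(x, y); mn <- pmin(x, y)
      s <- ifelse(m == 0, 0,
                  ifelse(is.infinite(m), Inf,
                         m * (1 + (mn / m)^a)^(1 / a)))
      exp(-s)
    },
    frank = {
      -log1p(expm1(-a * u) * expm1(-a * v) / expm1(-a)) / a
    }
  )
  # exact boundaries (also repairs any 0 * Inf artefacts)
  out[u == 0 | v == 0] <- 0
  out[v == 1] <- u[v == 1]
  out[u == 1] <- v[u == 1]
  pmin(pmax(out, 0), 1)
}

#' Copula density
#'
#' Evaluates the copula density \eqn{c(u,v;\alpha) = \partial^2 C / \partial
#' u \partial v} on the open unit square. Used for diagnostics and
#' validation; the discrete-margin likelihood uses rectangle probabilities
#' instead.
#'
#' @inheritParams copula_cdf
#' @return Nonnegative numeric vector.
#' @export
copula_density <- function(spec, u, v) {
  .check_spec(spec)
  .check_unit(u, "u", open = TRUE); .check_unit(v, "v", open = TRUE)
  k <- max(length(u), length(v))
  u <- rep_len(u, k); v <- rep_len(v, k)
  if (.is_indep(spec)) return(rep(1, k))
  a <- spec$alpha
  switch(spec$family,
    clayton = {
      (a + 1) * (u * v)^(-(a + 1)) * (u^(-a) + v^(-a) - 1)^(-1 / a - 2)
    },
    gumbel = {
      x <- -log(u); y <- -log(v)
      S <- x^a + y^a
      C <- exp(-S^(1 / a))
      C * S^(2 / a - 2) * (x * y)^(a - 1) * (1 + (a - 1) * S^(-1 / a)) / (u * v)
    },
    frank = {
      em <- expm1(-a)
      # -a*em > 0 for every valid alpha, so the ratio is positive
      -a * em * exp(-a * (u + v)) /
        (em + expm1(-a * u) * expm1(-a * v))^2
    }
  )
}

#' Conditional copula (h-function)
#'
#' Evaluates \eqn{h(u \mid v) = \partial C(u,v;\alpha) / \partial v =
#' P(U \le u \mid V = v)}.
#'
#' @inheritParams copula_cdf
#' @param u Numeric vector in \eqn{[0, 1]}.
#' @param v Numeric vector strictly inside \eqn{(0, 1)}.
#' @return Numeric vector in \eqn{[0, 1]}, nondecreasing in `u`.
#' @export
copula_hfun <- function(spec, u, v) {
  .check_spec(spec)
  .check_unit(u, "u"); .check_unit(v, "v", open = TRUE)
  k <- max(length(u), length(v))
  u <- rep_len(u, k); v <- rep_len(v, k)
  if (.is_indep(spec)) return(u)
  a <- spec$alpha
  out <- switch(spec$family,
    clayton = {
      v^(-a - 1) * (u^(-a) + v^(-a) - 1)^(-1 / a - 1)
    },
    gumbel = {
      x <- -log(u); y <- -log(v)
      S <- x^a + y^a
      exp(-S^(1 / a)) * S^(1 / a - 1) * y^(a - 1) / v
    },
    frank = {
      A <- expm1(-a * u); B <- expm1(-a * v)
      A * exp(-a * v) / (expm1(-a) + A * B)
    }
  )
  out[u == 0] <- 0
  out[u == 1] <- 1
  pmin(pmax(out, 0), 1)
}

#' Inverse conditional copula (h-inverse)
#'
#' Solves \eqn{h(u \mid v) = p} for \eqn{u}; the workhorse of sequential
#' simulation of the latent uniform Markov chain. Closed form for Clayton
#' and Frank; bracketed root-finding (tolerance 1e-12) for Gumbel.
#'
#' @inheritParams copula_cdf
#' @param p Numeric vector strictly inside \eqn{(0, 1)}.
#' @param v Numeric vector strictly inside \eqn{(0, 1)}.
#' @return Numeric vector `u` with `copula_hfun(spec, u, v) == p` to within
#'   1e-10.
#' @export
copula_hinv <- function(spec, p, v) {
  .check_spec(spec)
  .check_unit(p, "p", open = TRUE); .check_unit(v, "v", open = TRUE)
  k <- max(length(p), length(v))
  p <- rep_len(p, k); v <- rep_len(v, k)
  if (.is_indep(spec)) return(p)
  a <- spec$alpha
  switch(spec$family,
    clayton = {
      u <- ((p * v^(a + 1))^(-a / (a + 1)) - v^(-a) + 1)^(-1 / a)
      pmin(pmax(u, 1e-15), 1 - 1e-15)
    },
    frank = {
      B <- expm1(-a * v)
      A <- p * expm1(-a) / (B + 1 - p * B)
      u <- -log1p(A) / a
      pmin(pmax(u, 1e-15), 1 - 1e-15)
    },
    gumbel = {
      vapply(seq_len(k), function(i) {
        f <- function(u) copula_hfun(spec, u, v[i]) - p[i]
        lo <- 1e-12; hi <- 1 - 1e-12
        flo <- f(lo); fhi <- f(hi)
        if (flo > 0) return(lo)
        if (fhi < 0) return(hi)
        r <- stats::uniroot(f, c(lo, hi), f.lower = flo, f.upper = fhi,
                            tol = 1e-12, maxiter = 200L)
        if (abs(r$f.root) > 1e-8)
          stop(sprintf("Gumbel h-inverse failed to converge at p=%g, v=%g (residual %g)",
                       p[i], v[i], r$f.root))
        r$root
      }, numeric(1))
    }
  )
}

# First-order Debye function D1(x) = (1/x) int_0^x t/(e^t - 1) dt,
# by adaptive quadrature; D1(-x) = D1(x) + x/2.
.debye1 <- function(x) {
  if (x == 0) return(1)
  if (x < 0) return(.debye1(-x) - x / 2)
  f <- function(t) ifelse(t == 0, 1, t / expm1(t))
  q <- stats::integrate(f, 0, x, rel.tol = 1e-12, abs.tol = 1e-12)
  q$value / x
}

#' Kendall's tau implied by a copula parameter
#'
#' Clayton: \eqn{\tau = \alpha/(\alpha+2)}; Gumbel: \eqn{\tau = 1 - 1/\alpha};
#' Frank: \eqn{\tau = 1 - (4/\alpha)(1 - D_1(\alpha))} with \eqn{D_1} the
#' first-order Debye function (numeric quadrature).
#'
#' @param spec A [copula_spec()].
#' @return Kendall's tau, a scalar in \eqn{(-1, 1)}.
#' @export
param_to_tau <- function(spec) {
  .check_spec(spec)
  a <- spec$alpha
  if (.is_indep(spec)) return(0)
  switch(spec$family,
    clayton = a / (a + 2),
    gumbel  = 1 - 1 / a,
    frank   = 1 - (4 / a) * (1 - .debye1(a))
  )
}

#' Copula parameter for a target Kendall's tau
#'
#' Inverts the tau relations of [param_to_tau()]: closed form for Clayton
#' (\eqn{\alpha = 2\tau/(1-\tau)}) and Gumbel (\eqn{\alpha = 1/(1-\tau)}),
#' bracketed root-finding for Frank.
#'
#' @param family One of `"clayton"`, `"gumbel"`, `"frank"`.
#' @param tau Target Kendall's tau. Attainable ranges: Clayton/Gumbel
#'   `(0, 1)`; Frank `(-1, 1)` excluding 0.
#' @return The dependence parameter `alpha`.
#' @examples
#' tau_to_param("clayton", 0.8)  # 8
#' tau_to_param("gumbel", 0.5)   # 2
#' @export
tau_to_param <- function(family = c("clayton", "gumbel", "frank"), tau) {
  family <- match.arg(family)
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau))
    stop("`tau` must be a single finite numeric value")
  if (family %in% c("clayton", "gumbel")) {
    if (tau <= 0 || tau >= 1)
      stop(sprintf("tau = %g is unattainable for the %s copula (need 0 < tau < 1)",
                   tau, family))
  } else if (tau <= -1 || tau >= 1 || tau == 0) {
    stop("Frank copula requires tau in (-1, 1), tau != 0")
  }
  switch(family,
    clayton = 2 * tau / (1 - tau),
    gumbel  = 1 / (1 - tau),
    frank   = {
      g <- function(a) 1 - (4 / a) * (1 - .debye1(a)) - tau
      lo <- sign(tau) * 1e-8; hi <- sign(tau) * 4
      while (sign(tau) * g(hi) < 0 && abs(hi) < 1e6) hi <- hi * 2
      stats::uniroot(g, sort(c(lo, hi)), tol = 1e-12)$root
    }
  )
}

#' Tail-dependence coefficients
#'
#' Lower/upper tail dependence: Clayton \eqn{(2^{-1/\alpha}, 0)}, Gumbel
#' \eqn{(0, 2 - 2^{1/\alpha})}, Frank \eqn{(0, 0)}.
#'
#' @param spec A [copula_spec()].
#' @return Named numeric vector `c(lower=, upper=)` in \eqn{[0,1]^2}.
#' @export
tail_dependence <- function(spec) {
  .check_spec(spec)
  a <- spec$alpha
  if (.is_indep(spec)) return(c(lower = 0, upper = 0))
  switch(spec$family,
    clayton = c(lower = 2^(-1 / a), upper = 0),
    gumbel  = c(lower = 0, upper = 2 - 2^(1 / a)),
    frank   = c(lower = 0, upper = 0)
  )
}
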