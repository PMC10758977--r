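# Shared oracles and fixture builders. Oracles are deliberately independent
# of the code paths they check: finite differences of the CDF instead of
# the analytic h-function/density, exhaustive enumeration instead of the
# assembled likelihood.

# central finite difference of the copula CDF in v (h-function oracle)
fd_hfun <- function(spec, u, v, eps = 1e-6) {
  (copula_cdf(spec, u, v + eps) - copula_cdf(spec, u, v - eps)) / (2 * eps)
}

# central mixed partial of the copula CDF (density oracle)
fd_density <- function(spec, u, v, eps = 1e-5) {
  (copula_cdf(spec, u + eps, v + eps) - copula_cdf(spec, u + eps, v - eps) -
   copula_cdf(spec, u - eps, v + eps) + copula_cdf(spec, u - eps, v - eps)) /
    (4 * eps^2)
}

# one spec per family at a moderate-dependence parameter
family_specs <- function() list(
  clayton = copula_spec("clayton", 2),
  gumbel  = copula_spec("gumbel", 2),
  frank   = copula_spec("frank", 4)
)

# tiny fixed-design series for likelihood tests (deterministic covariates)
tiny_series <- function(y, n = rep(3L, length(y))) {
  Tt <- length(y)
  X <- cbind(1, seq(0, 1, length.out = Tt), rep(c(0.2, 0.8), length.out = Tt))
  binomial_series(y, n, X)
}

# exhaustive-enumeration total probability: sum over all outcome sequences
# of exp(loglik) for a T-point series with fixed n, X
enumeration_total <- function(spec, margin, n_each, Tt) {
  grid <- do.call(expand.grid, rep(list(0:n_each), Tt))
  tot <- 0
  for (i in seq_len(nrow(grid))) {
    s <- tiny_series(as.integer(grid[i, ]), n = rep(n_each, Tt))
    tot <- tot + exp(as.numeric(cmc_loglik(spec, margin, s)))
  }
  tot
}

# independent binomial-logistic log-likelihood (oracle for the
# independence limit)
indep_loglik <- function(margin, series) {
  pi <- plogis(drop(series$X %*% margin$beta))
  sum(dbinom(series$y, series$n, pi, log = TRUE))
}
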