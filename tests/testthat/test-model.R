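# The Markov chain likelihood: PIT bounds, rectangle/transition
# probabilities against enumeration oracles, likelihood assembly,
# score, MLE behaviour, prediction, metrics.

test_that("pit_bounds returns the CDF-jump rectangle corners", {
  m <- margin_model(c(0))  # pi = 0.5 everywhere
  s <- binomial_series(c(1, 1, 0, 2), rep(2L, 4), matrix(1, 4, 1))
  b <- pit_bounds(m, s, 2)
  expect_equal(b$u, 0.75); expect_equal(b$u_minus, 0.25)
  expect_equal(b$v, 0.75); expect_equal(b$v_minus, 0.25)
  # y = 0 gives the F(-1) = 0 corner; y = n gives u = 1
  b3 <- pit_bounds(m, s, 3)
  expect_equal(b3$u_minus, 0)
  b4 <- pit_bounds(m, s, 4)
  expect_equal(b4$u, 1)
  expect_equal(b4$v_minus, 0)
  # jump sizes equal the pmf
  expect_equal(b$u - b$u_minus, binom_pmf(1, 2, 0.5))
  expect_error(pit_bounds(m, s, 1), "2 <= t <= T")
})

test_that("rectangle probabilities factorize at independence and sum to 1", {
  m <- margin_model(c(-0.4))
  pi <- plogis(-0.4)
  indep <- copula_spec("frank", 1e-8)
  grid <- expand.grid(yt = 0:4, ytm = 0:4)
  b <- list(u = binom_cdf(grid$yt, 4, pi), v = binom_cdf(grid$ytm, 4, pi),
            u_minus = binom_cdf(grid$yt - 1, 4, pi),
            v_minus = binom_cdf(grid$ytm - 1, 4, pi))
  expect_equal(rectangle_prob(indep, b),
               binom_pmf(grid$yt, 4, pi) * binom_pmf(grid$ytm, 4, pi),
               tolerance = 1e-8)
  for (spec in family_specs()) {
    dc <- rectangle_prob(spec, b)
    expect_true(all(dc >= 0))
    expect_equal(sum(dc), 1, tolerance = 1e-10)
  }
})

test_that("boundary rectangle reduces to the corner identity chain", {
  # y_t = n_t and y_{t-1} = n_{t-1}: C(1,1) - C(1,v-) - C(u-,1) + C(u-,v-)
  # = 1 - v- - u- + C(u-, v-), brute-checked for n = 1 and 2
  spec <- copula_spec("clayton", 2)
  for (n in 1:2) {
    pi <- 0.5
    um <- binom_cdf(n - 1, n, pi); vm <- binom_cdf(n - 1, n, pi)
    b <- list(u = 1, v = 1, u_minus = um, v_minus = vm)
    expect_equal(rectangle_prob(spec, b),
                 1 - vm - um + copula_cdf(spec, um, vm), tolerance = 1e-12)
  }
})

test_that("transition pmf normalizes, degenerates at independence, and orders stochastically", {
  m <- margin_model(c(-1, 0.5))
  s <- binomial_series(c(3, 6), c(10L, 10L), cbind(1, c(0.5, 1.2)))
  alphas <- list(clayton = c(0.5, 2, 8), gumbel = c(1.25, 2, 6),
                 frank = c(-5, 2, 5))
  for (fam in names(alphas)) {
    for (a in alphas[[fam]]) {
      p <- transition_pmf(copula_spec(fam, a), m, s, 2, 0:10)
      expect_true(all(p >= 0))
      expect_equal(sum(p), 1, tolerance = 1e-8)
    }
  }
  pi2 <- success_prob(m, s$X[2, ])
  p_ind <- transition_pmf(copula_spec("frank", 1e-8), m, s, 2, 0:10)
  expect_equal(p_ind, binom_pmf(0:10, 10, pi2), tolerance = 1e-8)
  # strong positive dependence + high previous count shifts mass upward
  s_hi <- binomial_series(c(10, 5), c(10L, 10L), cbind(1, c(0.5, 1.2)))
  p_dep <- transition_pmf(copula_spec("frank", 30), m, s_hi, 2, 0:10)
  expect_gt(sum(0:10 * p_dep), 10 * pi2)
  expect_error(transition_pmf(copula_spec("frank", 2), m, s, 2, 11), "\\[0, n_t\\]")
})

test_that("loglik equals the independent logistic likelihood at the independence limit", {
  set.seed(401)
  d <- sim_design("frank", T = 120, beta = c(-2, 0.3, -0.5), alpha = 1e-8)
  s <- generate_series(d, seed = 7)
  m <- margin_model(c(-2, 0.3, -0.5))
  expect_equal(as.numeric(cmc_loglik(copula_spec("frank", 1e-8), m, s)),
               indep_loglik(m, s), tolerance = 1e-6)
})

test_that("conditional likelihood of a two-point series is log of one rectangle", {
  m <- margin_model(c(-0.3, 0.2))
  s <- binomial_series(c(2, 4), c(6L, 8L), cbind(1, c(0.1, 0.9)))
  for (spec in family_specs()) {
    b <- pit_bounds(m, s, 2)
    # full likelihood telescopes: log f1 + log DC2 - log f1 = log DC2
    expect_equal(as.numeric(cmc_loglik(spec, m, s)),
                 log(rectangle_prob(spec, b)), tolerance = 1e-12)
    # include_first adds exactly log f1(y1)
    expect_equal(as.numeric(cmc_loglik(spec, m, s)) -
                   as.numeric(cmc_loglik(spec, m, s, include_first = FALSE)),
                 binom_pmf(2, 6, success_prob(m, s$X[1, ]), log = TRUE),
                 tolerance = 1e-12)
  }
})

test_that("exp(loglik) sums to 1 over all outcome sequences (T = 3, n = 3)", {
  m <- margin_model(c(-0.5, 0.8, -0.3))
  for (spec in family_specs())
    expect_equal(enumeration_total(spec, m, n_each = 3L, Tt = 3), 1,
                 tolerance = 1e-8)
})

test_that("numerical score matches finite differences and has zero mean at truth", {
  d <- sim_design("clayton", T = 60, beta = c(-2, 0.3, -0.5), alpha = 2)
  spec <- copula_spec("clayton", 2)
  m <- margin_model(c(-2, 0.3, -0.5))
  # self-consistency with an independent step size
  s <- generate_series(d, seed = 5)
  g1 <- cmc_score(spec, m, s, eps = 1e-6)
  g2 <- cmc_score(spec, m, s, eps = 1e-5)
  expect_equal(g1, g2, tolerance = 1e-3)
  # E[score at truth] = 0, within 3 Monte-Carlo standard errors
  B <- 200
  G <- t(vapply(seq_len(B), function(b) {
    cmc_score(spec, m, generate_series(d, seed = 1000 + b))
  }, numeric(4)))
  mc_se <- apply(G, 2, sd) / sqrt(B)
  expect_true(all(abs(colMeans(G)) < 3 * mc_se))
})

test_that("fit recovers the independent logistic MLE under independence", {
  set.seed(402)
  d <- sim_design("frank", T = 300, beta = c(-2, 0.3, -0.5), alpha = 1e-8)
  s <- generate_series(d, seed = 31)
  fit <- suppressWarnings(cmc_fit(s, "frank"))
  glm_fit <- glm(cbind(y, n - y) ~ s$X[, -1], family = binomial,
                 data = list(y = s$y, n = s$n))
  glm_se <- sqrt(diag(vcov(glm_fit)))
  expect_true(fit$converged)
  expect_true(all(abs(fit$beta_hat - coef(glm_fit)) < 2 * glm_se))
})

test_that("fit is stable across initializations and its gradient vanishes at the MLE", {
  d <- sim_design("clayton", T = 150, beta = c(-2, 0.3, -0.5), alpha = 2)
  s <- generate_series(d, seed = 77)
  set.seed(601)
  starts <- c(list(list(start = "glm", alpha0 = 0.3),
                   list(start = "glm", alpha0 = 4)),
              lapply(1:3, function(i) {
                list(start = c(-2, 0.3, -0.5) * (1 + runif(3, -0.3, 0.3)),
                     alpha0 = runif(1, 0.3, 6))
              }))
  fits <- lapply(starts, function(a) suppressWarnings(
    do.call(cmc_fit, c(list(s, "clayton"), a))))
  lls <- vapply(fits, `[[`, numeric(1), "loglik")
  expect_true(all(abs(lls - lls[1]) < 1e-6))
  best <- fits[[1]]
  g <- cmc_score(copula_spec("clayton", best$alpha_hat),
                 margin_model(best$beta_hat), s)
  # scaled first-order condition
  expect_lt(max(abs(g)) / max(1, abs(best$loglik)), 1e-4)
})

test_that("fit rejects degenerate all-boundary series", {
  X <- cbind(1, runif(20))
  expect_error(cmc_fit(binomial_series(rep(0L, 20), rep(5L, 20), X), "clayton"),
               "degenerate series")
  expect_error(cmc_fit(binomial_series(rep(5L, 20), rep(5L, 20), X), "frank"),
               "degenerate series")
})

test_that("fitted standard errors are positive and finite on a healthy fit", {
  d <- sim_design("gumbel", T = 200, beta = c(-2, 0.3, -0.5), alpha = 2)
  s <- generate_series(d, seed = 9)
  fit <- cmc_fit(s, "gumbel")
  expect_true(fit$converged)
  expect_true(all(is.finite(fit$se)) && all(fit$se > 0))
  # truth within 4 SE of the single-series estimates
  expect_true(all(abs(fit$beta_hat - c(-2, 0.3, -0.5)) < 4 * fit$se[1:3]))
  expect_lt(abs(fit$alpha_hat - 2), 4 * fit$se["alpha"])
})

test_that("predictions are conditional means inside [0, n]", {
  d <- sim_design("frank", T = 60, beta = c(-2, 0.3, -0.5), alpha = 5,
                  n_range = c(20L, 40L))
  s <- generate_series(d, seed = 21)
  fit <- suppressWarnings(cmc_fit(s, "frank"))
  yhat <- predict(fit, s)
  expect_length(yhat, s$T)
  expect_true(all(yhat >= 0 & yhat <= s$n))
  # independence limit: yhat_t = n_t * pi_t
  m <- margin_model(c(-2, 0.3, -0.5))
  fit_ind <- fit; fit_ind$alpha_hat <- 1e-8
  fit_ind$beta_hat <- c(-2, 0.3, -0.5)
  pi <- success_prob(m, s$X)
  expect_equal(predict(fit_ind, s), s$n * pi, tolerance = 1e-7)
  # positive dependence pulls the forecast toward a high previous count
  s_hi <- binomial_series(c(30L, 10L), c(30L, 30L), cbind(1, c(5, 5), c(0.5, 0.5)))
  fit_dep <- fit; fit_dep$alpha_hat <- 5; fit_dep$beta_hat <- c(-2, 0.3, -0.5)
  pi2 <- success_prob(m, s_hi$X[2, ])
  expect_gt(predict(fit_dep, s_hi)[2], 30 * pi2)
})

test_that("fit_metrics computes MSE and zero-excluded MAPE", {
  expect_equal(fit_metrics(c(10, 20), c(10, 20)), list(mse = 0, mape = 0))
  m <- fit_metrics(c(10, 20), c(11, 18))
  expect_equal(m$mse, 2.5)
  expect_equal(m$mape, 0.1)
  # permutation invariance
  perm <- c(2, 1)
  expect_equal(fit_metrics(c(10, 20)[perm], c(11, 18)[perm]), m)
  # zero counts excluded from MAPE only
  m0 <- fit_metrics(c(0, 10), c(1, 11))
  expect_equal(m0$mape, 0.1)
  expect_equal(m0$mse, 1)
  expect_error(fit_metrics(c(0, 0), c(1, 1)), "MAPE undefined")
  expect_error(fit_metrics(1:3, 1:2), "equal length")
})
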