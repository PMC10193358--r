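# Metropolis-within-Gibbs sampler: conditional posteriors, update
# mechanics, and distributional correctness.

make_scalar_data <- function(y) {
  regression_data(y, X1 = matrix(1, length(y), 1,
                                 dimnames = list(NULL, "(Intercept)")))
}

test_that("beta conditional reduces to the Poisson log-likelihood at nu = 1", {
  set.seed(41)
  X <- cbind(1, rnorm(40))
  y <- rpois(40, exp(0.5 + 0.3 * X[, 2]))
  d <- regression_data(y, X)
  prior <- prior_spec(beta_var = 1e8)  # effectively flat
  b1 <- c(0.4, 0.2); b2 <- c(0.6, 0.35)
  # differences of the conditional must match Poisson log-lik differences
  dc <- log_cond_beta(b2, gamma = 0, data = d, prior = prior) -
    log_cond_beta(b1, gamma = 0, data = d, prior = prior)
  dp <- sum(dpois(y, exp(X %*% b2), log = TRUE)) -
    sum(dpois(y, exp(X %*% b1), log = TRUE))
  dprior <- sum(-0.5 * (b2^2 - b1^2) / 1e8)
  expect_equal(dc, dp + dprior, tolerance = 1e-8)
})

test_that("conditionals match a direct evaluation from the pmf", {
  d <- make_scalar_data(2L)
  prior <- prior_spec()
  beta <- log(2.5); gamma <- log(1.5)
  lp <- dmpcmp(2, mu = 2.5, nu = 1.5, trunc = trunc_series(60), log = TRUE)
  direct_b <- lp + sum(bidisperse:::dnorm_log_vec(beta, 0, 1e5))
  direct_g <- lp + sum(bidisperse:::dnorm_log_vec(gamma, 0, 1e5))
  expect_equal(log_cond_beta(beta, gamma, d, prior, k = 60L), direct_b,
               tolerance = 1e-10)
  expect_equal(log_cond_gamma(gamma, beta, d, prior, k = 60L), direct_g,
               tolerance = 1e-10)
})

test_that("the dispersion-specific data term vanishes for all-zero responses", {
  # log 0! = 0, so the likelihood parts of the two conditionals coincide
  d <- make_scalar_data(c(0L, 0L, 0L))
  prior <- prior_spec()
  beta <- log(0.8); gamma <- log(2)
  lik_b <- log_cond_beta(beta, gamma, d, prior) -
    sum(bidisperse:::dnorm_log_vec(beta, 0, 1e5))
  lik_g <- log_cond_gamma(gamma, beta, d, prior) -
    sum(bidisperse:::dnorm_log_vec(gamma, 0, 1e5))
  expect_equal(lik_b, lik_g, tolerance = 1e-12)
})

test_that("finite differences of the gamma conditional match the analytic gradient", {
  set.seed(42)
  y <- rmpcmp(25, 2.2, 1)
  d <- make_scalar_data(y)
  prior <- prior_spec(gamma_var = 0.25)
  beta <- log(2.2); gamma0 <- 0  # nu = 1
  k <- 60
  # analytic: d/dgamma = nu * sum_i [(y_i - mu) dll/dnu + E log r! - log y_i!]
  #           - gamma / var,  with dll/dnu = cov(r, log r!) / var(r)
  ll <- solve_lambda_bisection(exp(beta), 1, trunc_series(k))$log_lambda
  r <- 0:k
  mo <- moments_brute(ll, 1, k)
  lgf <- lgamma(r + 1)
  Elgf <- sum(lgf * mo$p)
  cov_rlgf <- sum(r * lgf * mo$p) - mo$mean * Elgf
  dll_dnu <- cov_rlgf / mo$var
  grad <- sum((y - exp(beta)) * dll_dnu + Elgf - lgamma(y + 1)) * 1 -
    gamma0 / 0.25
  h <- 1e-5
  fd <- (log_cond_gamma(gamma0 + h, beta, d, prior, k = k) -
           log_cond_gamma(gamma0 - h, beta, d, prior, k = k)) / (2 * h)
  expect_equal(fd, grad, tolerance = 1e-4)
})

test_that("an offset enters the mean model additively on the log scale", {
  set.seed(43)
  X <- cbind(1, rbinom(30, 1, 0.5))
  y <- rpois(30, 2)
  d0 <- regression_data(y, X)
  d2 <- regression_data(y, X, offset = rep(log(2), 30))
  beta <- c(0.1, 0.2)
  # doubling every mu via the offset = shifting the intercept by log 2
  expect_equal(log_cond_beta(beta, 0, d2, prior_spec()),
               log_cond_beta(beta + c(log(2), 0), 0, d0, prior_spec()) -
                 sum(bidisperse:::dnorm_log_vec(beta + c(log(2), 0), 0, 1e5)) +
                 sum(bidisperse:::dnorm_log_vec(beta, 0, 1e5)),
               tolerance = 1e-10)
})

test_that("fits are reproducible and the RNG stream is solver-invariant", {
  sim <- simulate_scenario("I", seed = 3, n = 60)
  cfg <- mcmc_config(150, warmup = 50, seed = 7, method = "bisection")
  f1 <- fit_mpcmp(sim$data, config = cfg)
  f2 <- fit_mpcmp(sim$data, config = cfg)
  expect_identical(f1$beta, f2$beta)
  expect_identical(f1$gamma, f2$gamma)

  # identical seeds consume identical randomness whatever the solver
  f3 <- fit_mpcmp(sim$data, config = cfg)
  state_bisection <- .Random.seed
  cfg_lk <- mcmc_config(150, warmup = 50, seed = 7, method = "lookup")
  f4 <- fit_mpcmp(sim$data, config = cfg_lk, table = test_table())
  state_lookup <- .Random.seed
  expect_identical(state_bisection, state_lookup)
})

test_that("sum-to-zero random effects hold exactly in every draw", {
  sim <- simulate_scenario("II", seed = 4, obs_per_individual = 10)
  fit <- fit_mpcmp(sim$data, prior_spec(gamma_var = 0.25),
                   mcmc_config(100, warmup = 50, seed = 5, method = "lookup"),
                   table = test_table())
  expect_lt(max(abs(rowSums(fit$theta))), 1e-10)
  expect_equal(dim(fit$theta), c(100L, 20L))
  expect_equal(dim(fit$gamma), c(100L, 20L))
})

test_that("posterior means recover the Poisson MLE under equidispersion", {
  set.seed(44)
  n <- 1000
  X <- cbind(1, rbinom(n, 1, 0.5), rnorm(n))
  beta_true <- c(0.8, -0.3, 0.2)
  y <- rpois(n, exp(X %*% beta_true))
  d <- regression_data(y, X)
  fit <- fit_mpcmp(d, prior_spec(),
                   mcmc_config(1500, warmup = 500, seed = 6,
                               method = "lookup"),
                   table = test_table())
  mle <- glm.fit(X, y, family = poisson())$coefficients
  s <- posterior_summary(fit)
  for (j in 1:3) {
    tol <- 3 * s$mcse[j] + 0.1 * s$sd[j]
    expect_lt(abs(s$mean[j] - mle[j]), tol)
  }
  # equidispersion should be recovered: log nu near 0
  expect_lt(abs(s$mean[4]), 3 * s$sd[4] + 0.1)
})

test_that("the sampled posterior matches a dense grid evaluation (detailed balance)", {
  set.seed(45)
  y <- rmpcmp(10, 3, 1.2)
  d <- make_scalar_data(y)
  prior <- prior_spec(beta_var = 4, gamma_var = 0.25)
  bg <- seq(log(mean(y) + 0.5) - 1.6, log(mean(y) + 0.5) + 1.6, length.out = 61)
  gg <- seq(-1.6, 1.6, length.out = 61)
  lp <- outer(bg, gg, Vectorize(function(b, g)
    log_cond_beta(b, g, d, prior, k = 60L) +
      sum(bidisperse:::dnorm_log_vec(g, 0, 0.25))))
  post <- exp(lp - max(lp))
  post <- post / sum(post)
  marg_gamma <- colSums(post)

  fit <- fit_mpcmp(d, prior,
                   mcmc_config(40000, warmup = 2000, seed = 8,
                               method = "bisection", k = 60L))
  # compare on 13 coarse gamma bins whose edges fall between grid nodes
  mid <- seq(5, 55, by = 5)
  edges <- c(-Inf, (gg[mid] + gg[mid + 1]) / 2, Inf)
  p_grid <- as.numeric(tapply(marg_gamma,
                              cut(gg, edges, include.lowest = TRUE), sum))
  p_mcmc <- as.numeric(table(cut(fit$gamma[, 1], edges,
                                 include.lowest = TRUE))) / nrow(fit$gamma)
  tv <- 0.5 * sum(abs(p_grid - p_mcmc))
  expect_lt(tv, 0.05)
})

test_that("solver failures reject the proposal instead of crashing", {
  # a table whose hull the chain will leave forces extrapolation, and the
  # bisection path must reject un-bracketable proposals quietly
  set.seed(46)
  y <- rmpcmp(30, 2, 1)
  d <- make_scalar_data(y)
  fit <- fit_mpcmp(d, prior_spec(),
                   mcmc_config(200, warmup = 100, seed = 9,
                               method = "bisection", k = 64L))
  expect_true(all(is.finite(fit$beta)))
})

test_that("multiple chains stack draws and report split R-hat", {
  sim <- simulate_scenario("I", seed = 10, n = 40)
  fit <- fit_mpcmp(sim$data, config = mcmc_config(200, warmup = 100,
                                                  seed = 11,
                                                  method = "bisection",
                                                  chains = 2))
  expect_equal(nrow(fit$beta), 400L)
  expect_length(fit$chain_fits, 2L)
  expect_true(all(is.finite(fit$rhat)))
})

test_that("HDI is the shortest interval and behaves under asymmetry", {
  x10 <- c(0, 0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 2, 5, 10)
  got <- hdi(x10, 0.5)
  # exhaustive oracle over all contiguous windows of ceiling(0.5 * 10) + 1
  xs <- sort(x10)
  w <- ceiling(0.5 * 10)
  widths <- xs[(w + 1):10] - xs[1:(10 - w)]
  i <- which.min(widths)
  expect_identical(got, c(xs[i], xs[i + w]))

  set.seed(47)
  xn <- rnorm(20000)
  expect_equal(hdi(xn, 0.9), qnorm(c(0.05, 0.95)), tolerance = 0.05)
  xe <- rexp(20000)
  h <- hdi(xe, 0.9)
  expect_lt(h[1], quantile(xe, 0.05))  # shifted toward the mode at 0
  expect_lt(h[2], quantile(xe, 0.95))
})

test_that("posterior_summary warns on very short chains", {
  sim <- simulate_scenario("I", seed = 12, n = 30)
  fit <- fit_mpcmp(sim$data, config = mcmc_config(50, warmup = 20, seed = 13,
                                                  method = "bisection"))
  expect_warning(posterior_summary(fit), "fewer than 100")
})
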