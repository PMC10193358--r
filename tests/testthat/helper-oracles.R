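# Independent oracles (plain-R brute force) and shared fixtures.

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

# direct series summation for log G, kept independent of the compiled path
logG_brute <- function(log_lambda, nu, k = 500) {
  r <- 0:k
  logsumexp(r * log_lambda - nu * lgamma(r + 1))
}

# brute-force moments of the truncated CMP
moments_brute <- function(log_lambda, nu, k = 500) {
  r <- 0:k
  lw <- r * log_lambda - nu * lgamma(r + 1)
  w <- exp(lw - logsumexp(lw))
  m1 <- sum(r * w)
  list(mean = m1, var = sum(r^2 * w) - m1^2, p = w)
}

# 200-iteration pure bisection on the mean constraint (no Newton), the
# high-precision solver oracle
bisect_oracle <- function(mu, nu, k = 200, lo = -30, hi = 30) {
  f <- function(ll) moments_brute(ll, nu, k)$mean - mu
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

# shared look-up tables, built once per test run
.tab_env <- new.env(parent = emptyenv())

# moderate grid covering the simulation scenarios, generous truncation
test_table <- function() {
  if (is.null(.tab_env$tab))
    .tab_env$tab <- build_lookup_table(
      lookup_grid(mu_max = 16, mu_step = 0.02, nu_max = 4, nu_step = 0.1),
      trunc_k = 64L)
  .tab_env$tab
}

# the default production grid (0.01 x 0.05 over [0.01,32] x [0,10])
default_table <- function() {
  if (is.null(.tab_env$default)) .tab_env$default <- build_lookup_table()
  .tab_env$default
}
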