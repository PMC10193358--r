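#' Log normalising constant of the CMP distribution
#'
#' Computes `log G(lambda, nu) = log sum_{r=0}^{k} lambda^r / (r!)^nu`,
#' the (truncated) normalising constant of the Conway-Maxwell-Poisson
#' distribution, by log-sum-exp so that no intermediate term overflows.
#'
#' @param log_lambda Numeric vector of log rates.
#' @param nu Dispersion parameter(s), `nu >= 0`; scalar or same length as
#'   `log_lambda`.  `nu = 1` is Poisson, `nu = 0` geometric, `nu > 1`
#'   underdispersed.
#' @param trunc A [trunc_series()] / [trunc_bound()] object; defaults to
#'   `trunc_series(60)` widened to cover `exp(log_lambda)` when `nu = 1`.
#' @return Numeric vector of `log G` values.
#' @examples
#' cmp_log_norm_const(log(2), nu = 1, trunc = trunc_series(400))  # = 2
#' @export
cmp_log_norm_const <- function(log_lambda, nu, trunc = NULL) {
  check_dist_args(log_lambda, nu)
  if (is.null(trunc)) trunc <- trunc_series(min(50000, max(60L, ceiling(2 * exp(max(log_lambda))))))
  stopifnot(inherits(trunc, "cmp_trunc"))
  .cpp_cmp_logG(as.numeric(log_lambda), as.numeric(nu), trunc$k)
}

#' Mean of the (truncated) CMP distribution given its rate
#'
#' Returns `sum_{r=0}^{k} r Pr(r | lambda, nu)` under the same truncation
#' as the normalising constant.  This is the left-hand side of the mean
#' constraint that the rate solvers invert.
#'
#' @inheritParams cmp_log_norm_const
#' @return Numeric vector of means.
#' @export
cmp_mean <- function(log_lambda, nu, trunc = NULL) {
  check_dist_args(log_lambda, nu)
  if (is.null(trunc)) trunc <- trunc_series(min(50000, max(60L, ceiling(2 * exp(max(log_lambda))))))
  stopifnot(inherits(trunc, "cmp_trunc"))
  .cpp_cmp_moments(as.numeric(log_lambda), as.numeric(nu), trunc$k)$mean
}

check_dist_args <- function(log_lambda, nu) {
  if (!all(is.finite(log_lambda)))
    stop("`log_lambda` must be finite", call. = FALSE)
  if (!all(is.finite(nu)) || any(nu < 0))
    stop("`nu` must be finite and >= 0", call. = FALSE)
  invisible(TRUE)
}

#' MPCMP probability mass function
#'
#' Density of the mean-parameterised Conway-Maxwell-Poisson distribution
#' with mean `mu` and dispersion `nu`.  The rate `lambda(mu, nu)` is
#' recovered from the mean constraint via [solve_lambda()] (or supplied
#' directly as a `rate` pair to skip the solve).
#'
#' @param x Vector of non-negative integer quantiles.
#' @param mu Mean, `mu > 0`.
#' @param nu Dispersion, `nu >= 0`; `nu = 1` Poisson, `nu < 1`
#'   overdispersed, `nu > 1` underdispersed.
#' @param trunc Truncation policy; see [trunc_series()].  Under
#'   [trunc_bound()] values of `x` above the bound are an error.
#' @param rate Optional list with `log_lambda` and `log_G` (as returned by
#'   [solve_lambda()]) solving the mean constraint for `(mu, nu, trunc)`.
#' @param method,table Passed to [solve_lambda()] when `rate` is missing.
#' @param log Return log-probabilities?
#' @return Vector of (log-)probabilities.
#' @examples
#' dmpcmp(0:5, mu = 2.5, nu = 1.5)
#' all.equal(dmpcmp(0:10, mu = 3, nu = 1), dpois(0:10, 3))
#' @export
dmpcmp <- function(x, mu, nu, trunc = NULL, rate = NULL,
                   method = "bisection", table = NULL, log = FALSE) {
  stopifnot(length(mu) == 1L, length(nu) == 1L, mu > 0, nu >= 0)
  trunc <- as_trunc(trunc, mu)
  x <- as.integer(x)
  if (any(x < 0)) stop("counts must be non-negative", call. = FALSE)
  if (trunc$mode == "bound" && any(x > trunc$k))
    stop("count outside the hard support bound k = ", trunc$k, call. = FALSE)
  if (is.null(rate))
    rate <- solve_lambda(mu, nu, method = method, trunc = trunc, table = table)
  out <- x * rate$log_lambda - nu * lgamma(x + 1) - rate$log_G
  out[x > trunc$k] <- -Inf  # series truncation: mass beyond k is dropped
  if (log) out else exp(out)
}

#' Variance of the MPCMP distribution
#'
#' Second central moment under the truncated pmf.  The variance-to-mean
#' ratio is below / at / above 1 according as `nu > 1`, `= 1`, `< 1`,
#' which is the diagnostic axis for under/overdispersion.
#'
#' @inheritParams dmpcmp
#' @return Scalar variance.
#' @export
mpcmp_variance <- function(mu, nu, trunc = NULL, rate = NULL,
                           method = "bisection", table = NULL) {
  stopifnot(length(mu) == 1L, length(nu) == 1L, mu > 0, nu >= 0)
  trunc <- as_trunc(trunc, mu)
  if (is.null(rate))
    rate <- solve_lambda(mu, nu, method = method, trunc = trunc, table = table)
  .cpp_cmp_moments(rate$log_lambda, nu, trunc$k)$var
}

#' Draw MPCMP variates
#'
#' Sampling is by inversion of the cumulative distribution on the truncated
#' support, so draws respect R's RNG state (`set.seed()` gives reproducible
#' sequences).  `mu` and `nu` are recycled to length `n`.
#'
#' @param n Number of draws.
#' @inheritParams dmpcmp
#' @return Integer vector of length `n`.
#' @examples
#' set.seed(1)
#' y <- rmpcmp(1000, mu = 3, nu = 1.5)
#' mean(y); var(y)  # variance < mean: underdispersed
#' @export
rmpcmp <- function(n, mu, nu, trunc = NULL, method = "bisection",
                   table = NULL) {
  stopifnot(n >= 1, all(mu > 0), all(nu >= 0))
  mu <- rep_len(as.numeric(mu), n)
  nu <- rep_len(as.numeric(nu), n)
  trunc <- as_trunc(trunc, mu)
  k <- trunc$k
  pairs <- unique(data.frame(mu = mu, nu = nu))
  key <- match(paste(mu, nu), paste(pairs$mu, pairs$nu))
  rate <- solve_lambda(pairs$mu, pairs$nu, method = method, trunc = trunc,
                       table = table)
  # pmf matrix over support 0..k for each unique (mu, nu) pair
  r <- 0:k
  lp <- outer(r, rate$log_lambda) - outer(lgamma(r + 1), pairs$nu) -
    rep(rate$log_G, each = k + 1)
  cdf <- apply(exp(lp), 2, cumsum)
  u <- runif(n)
  out <- integer(n)
  for (j in seq_len(nrow(pairs))) {
    idx <- which(key == j)
    out[idx] <- findInterval(u[idx], cdf[, j]) # counts how many cdf vals < u
  }
  pmin(out, k)
}
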