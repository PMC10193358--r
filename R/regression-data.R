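#' Bundle count-regression data for MPCMP fitting
#'
#' @param y Non-negative integer responses.
#' @param X1 Design matrix for the log-linear mean model (include the
#'   intercept column explicitly).
#' @param X2 Design matrix for the log-linear dispersion model; `NULL`
#'   means a single intercept (scalar dispersion).  For individual-level
#'   dispersion pass the group indicator matrix (one column per
#'   individual, see [group_design()]).
#' @param group Optional individual labels (factor/integer) attaching a
#'   random effect on the mean to each observation; recoded to contiguous
#'   `1..m`.
#' @param offset Optional offset added to the linear predictor of the
#'   mean (on the log scale).
#' @param support_bound Optional hard upper bound `y_tau` on the counts;
#'   when set, the series truncation is exactly `k = y_tau` and counts
#'   above it are rejected.
#' @return A `regression_data` object.
#' @export
regression_data <- function(y, X1, X2 = NULL, group = NULL, offset = NULL,
                            support_bound = NULL) {
  y <- as.integer(y)
  n <- length(y)
  if (any(is.na(y)) || any(y < 0))
    stop("responses must be non-negative integers", call. = FALSE)
  X1 <- as.matrix(X1)
  storage.mode(X1) <- "double"
  stopifnot(nrow(X1) == n)
  if (qr(X1)$rank < ncol(X1))
    stop("mean design matrix X1 is not of full column rank", call. = FALSE)
  if (is.null(X2)) X2 <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  X2 <- as.matrix(X2)
  storage.mode(X2) <- "double"
  stopifnot(nrow(X2) == n)
  if (qr(X2)$rank < ncol(X2))
    stop("dispersion design matrix X2 is not of full column rank", call. = FALSE)
  if (!is.null(group)) {
    group <- as.integer(factor(group))
    stopifnot(length(group) == n)
  }
  if (!is.null(offset)) {
    offset <- as.numeric(offset)
    stopifnot(length(offset) == n, all(is.finite(offset)))
  }
  if (!is.null(support_bound)) {
    support_bound <- as.integer(support_bound)
    stopifnot(support_bound >= 1L)
    if (any(y > support_bound))
      stop("responses exceed the declared support bound y_tau = ",
           support_bound, call. = FALSE)
  }
  structure(list(y = y, X1 = X1, X2 = X2, group = group, offset = offset,
                 support_bound = support_bound,
                 n = n, p = ncol(X1), q = ncol(X2),
                 m = if (is.null(group)) 0L else max(group)),
            class = "regression_data")
}

#' @export
print.regression_data <- function(x, ...) {
  cat(sprintf("<regression_data> n = %d, p = %d (mean), q = %d (dispersion)%s%s\n",
              x$n, x$p, x$q,
              if (x$m > 0) sprintf(", m = %d individuals", x$m) else "",
              if (!is.null(x$support_bound))
                sprintf(", support bound %d", x$support_bound) else ""))
  invisible(x)
}

#' Indicator design for individual-level dispersion
#'
#' One column per individual so that each dispersion coefficient is that
#' individual's `log nu_i` (updated component-wise by the sampler).
#'
#' @param group Individual labels.
#' @return A 0/1 matrix with one column per level.
#' @export
group_design <- function(group) {
  g <- factor(group)
  m <- stats::model.matrix(~ 0 + g)
  colnames(m) <- paste0("nu[", levels(g), "]")
  attr(m, "assign") <- NULL
  attr(m, "contrasts") <- NULL
  m
}

#' Prior specification for MPCMP regression
#'
#' Independent normal priors throughout: `beta ~ N(beta_mean, beta_var)`
#' componentwise (variance `1e5` reproduces the conventional vague choice),
#' `gamma ~ N(gamma_mean, gamma_var)` on the log-dispersion coefficients
#' (a lognormal prior on `nu`; `gamma_var = 0.25` is the usual choice for
#' individual-level dispersions, centring them on equidispersion), and
#' `theta ~ N(0, theta_var)` for the random effects on the mean
#' (`0.5 * log 2` puts doubling/halving of the rate in the tail).
#'
#' @param beta_mean,beta_var Mean/variance for the mean-model coefficients
#'   (recycled).
#' @param gamma_mean,gamma_var Mean/variance for the dispersion-model
#'   coefficients (recycled).
#' @param theta_var Variance of the random effects on the mean.
#' @return A `cmp_prior` object.
#' @export
prior_spec <- function(beta_mean = 0, beta_var = 1e5,
                       gamma_mean = 0, gamma_var = 1e5,
                       theta_var = 0.5 * log(2)) {
  stopifnot(all(beta_var > 0), all(gamma_var > 0), theta_var > 0)
  structure(list(beta_mean = beta_mean, beta_var = beta_var,
                 gamma_mean = gamma_mean, gamma_var = gamma_var,
                 theta_var = theta_var), class = "cmp_prior")
}

#' MCMC configuration
#'
#' @param iterations Post-warmup iterations to run.
#' @param warmup Warmup iterations (adaptation happens here and is frozen
#'   afterwards to preserve detailed balance).
#' @param seed RNG seed; all sampler randomness flows from it, and the
#'   proposal stream does not depend on the solver method, so chains run
#'   with different solvers share identical proposals.
#' @param method Rate solver used inside the sampler: `"lookup"`,
#'   `"bisection"` or `"polynomial"`.
#' @param thin Keep every `thin`-th post-warmup draw.
#' @param sum_to_zero Enforce the sum-to-zero identifiability constraint on
#'   the random effects by sampling `m - 1` free components (exact in every
#'   draw, not post-hoc centring).
#' @param k Series truncation for the likelihood; defaults to the support
#'   bound when one is declared, else the look-up table's `trunc_k`, else
#'   `max(60, ceiling(6 * max(y)))` (a mean ceiling of three times the
#'   largest count, doubled).
#' @param adapt Robbins-Monro proposal-scale adaptation during warmup,
#'   targeting acceptance 0.234 for blocks and 0.44 for scalar updates.
#' @param chains Number of independent chains (run sequentially; chain `c`
#'   uses seed `seed + c - 1`).
#' @return A `cmp_mcmc_config` object.
#' @export
mcmc_config <- function(iterations = 5000, warmup = 1000, seed = 1L,
                        method = c("lookup", "bisection", "polynomial"),
                        thin = 1L, sum_to_zero = TRUE, k = NULL,
                        adapt = TRUE, chains = 1L) {
  method <- match.arg(method)
  stopifnot(iterations > 0, warmup >= 0, thin >= 1)
  structure(list(iterations = as.integer(iterations),
                 warmup = as.integer(warmup), seed = as.integer(seed),
                 method = method, thin = as.integer(thin),
                 sum_to_zero = isTRUE(sum_to_zero),
                 k = if (is.null(k)) NULL else as.integer(k),
                 adapt = isTRUE(adapt), chains = as.integer(chains)),
            class = "cmp_mcmc_config")
}
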