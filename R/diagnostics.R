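# Importance-ratio diagnostic for the look-up approximation, and timing
# comparisons across solver methods.

#' Importance ratios of the exact versus look-up posterior
#'
#' For each retained draw `(beta, gamma, theta)` of a chain run with the
#' look-up solver, evaluates the unnormalised exact posterior (rate from
#' the reference solver) and the unnormalised approximate posterior (rate
#' interpolated from the table) and returns the ratio
#' `r = pi_exact / pi_approx`.  Priors and the `nu log y!` term are common
#' to both and cancel, so the log-ratio reduces to
#' `sum_i [ y_i (log lambda_i - log lambda~_i) - (log G_i - log G~_i) ]`.
#' Ratios are computed in log space and stabilised by subtracting the
#' maximum before exponentiation; [approx_ess()] is invariant to that
#' rescaling, so the diagnostic is exact.
#'
#' @param fit An `mpcmp_fit` run with `method = "lookup"`.
#' @param data The [regression_data()] the chain was fitted to.
#' @param reference Exact solver for the numerator: `"bisection"` or
#'   `"polynomial"` (or `"lookup"` for a self-comparison, in which case
#'   every ratio is exactly 1).
#' @param K Number of draws to use (default: the last 1000 retained).
#' @param table Look-up table; defaults to the one stored in the fit.
#' @return A `cmp_importance` object: stabilised `ratios`, `log_ratios`,
#'   `m_e`, `K`, and `reference`.  Draws where the reference solver fails
#'   are dropped with a warning (reducing `K`).
#' @export
importance_ratios <- function(fit, data,
                              reference = c("bisection", "polynomial", "lookup"),
                              K = 1000L, table = NULL) {
  stopifnot(inherits(fit, "mpcmp_fit"), inherits(data, "regression_data"))
  reference <- match.arg(reference)
  if (is.null(table)) table <- fit$table
  if (is.null(table))
    stop("no look-up table stored in the fit; pass `table`", call. = FALSE)
  if (fit$method != "lookup")
    warning("chain was not run with the look-up solver; ",
            "the diagnostic measures nothing in that case")
  ndraws <- nrow(fit$beta)
  use <- seq.int(max(1L, ndraws - K + 1L), ndraws)
  k <- fit$k
  y <- data$y
  log_r <- vapply(use, function(t) {
    beta <- fit$beta[t, ]
    gamma <- fit$gamma[t, ]
    theta <- if (is.null(fit$theta)) NULL else fit$theta[t, ]
    mu <- mpcmp_mu(data, beta, theta)
    nu <- as.numeric(exp(data$X2 %*% gamma))
    ll_tilde <- .cpp_lookup_loglambda(table$values, table$mu_nodes,
                                      table$nu_nodes,
                                      table$grid$spacing == "log-mu",
                                      mu, nu)$log_lambda
    ll_exact <- switch(reference,
      bisection = .cpp_solve_bisection(mu, nu, k, 1e-10)$log_lambda,
      polynomial = .cpp_solve_polynomial(mu, nu, k)$log_lambda,
      lookup = ll_tilde)
    if (anyNA(ll_exact)) return(NA_real_)
    lG_tilde <- .cpp_cmp_logG(ll_tilde, nu, k)
    lG_exact <- .cpp_cmp_logG(ll_exact, nu, k)
    sum(y * (ll_exact - ll_tilde) - (lG_exact - lG_tilde))
  }, numeric(1))
  if (anyNA(log_r)) {
    nbad <- sum(is.na(log_r))
    warning(nbad, " draw(s) dropped: reference solver failed there")
    log_r <- log_r[!is.na(log_r)]
  }
  ratios <- exp(log_r - max(log_r))
  structure(list(ratios = ratios, log_ratios = log_r,
                 m_e = approx_ess(ratios), K = length(ratios),
                 reference = reference),
            class = "cmp_importance")
}

#' @export
print.cmp_importance <- function(x, ...) {
  cat(sprintf(
    "<cmp_importance> m_e = %.1f of K = %d (reference: %s)\n",
    x$m_e, x$K, x$reference))
  invisible(x)
}

#' Approximate effective sample size of an importance-weighted sample
#'
#' `m_e = (sum r)^2 / sum r^2` for positive ratios `r`.  Equals `K` iff
#' all ratios are equal, approaches 1 as one ratio dominates, and is
#' invariant to rescaling all ratios by a positive constant.  It measures
#' how much posterior information the look-up approximation preserves; it
#' is not the autocorrelation-based MCMC effective sample size.
#'
#' @param ratios Positive importance ratios.
#' @return Scalar in `[1, length(ratios)]`.
#' @examples
#' approx_ess(rep(3, 100))     # 100
#' approx_ess(c(1, 1, 2))      # 16/6
#' @export
approx_ess <- function(ratios) {
  if (inherits(ratios, "cmp_importance")) ratios <- ratios$ratios
  if (length(ratios) == 0L) stop("empty ratio vector", call. = FALSE)
  if (!all(is.finite(ratios)) || any(ratios <= 0))
    stop("ratios must be finite and positive", call. = FALSE)
  sum(ratios)^2 / sum(ratios^2)
}

#' Timing comparison across solver methods
#'
#' Summarises the per-iteration wall-time traces of one or more fits and,
#' when a look-up fit is among them, reports the crossover iteration at
#' which the cumulative look-up time (including the table build time)
#' first undercuts each alternative.  Timings are recorded but never
#' asserted: they are hardware-dependent.
#'
#' @param fits Named list of `mpcmp_fit` objects (names = method labels),
#'   or a single fit.
#' @param build_time Seconds spent building the look-up table, added to
#'   the look-up method's cumulative curve.
#' @return A `cmp_timing` list: `summary` data frame (method, mean, sd,
#'   total seconds per iteration), `cumulative` (list of cumulative-time
#'   vectors), and `crossover` (named vector of iterations, `NA` when the
#'   look-up curve never undercuts within the run).
#' @export
timing_report <- function(fits, build_time = 0) {
  if (inherits(fits, "mpcmp_fit")) fits <- stats::setNames(list(fits), fits$method)
  stopifnot(length(fits) >= 1L, !is.null(names(fits)))
  times <- lapply(fits, `[[`, "iter_time")
  summary <- data.frame(
    method = names(fits),
    mean = vapply(times, mean, numeric(1)),
    sd = vapply(times, sd, numeric(1)),
    total = vapply(times, sum, numeric(1)),
    row.names = NULL)
  cum <- lapply(times, cumsum)
  crossover <- NULL
  lk <- which(names(fits) == "lookup")
  if (length(lk) == 1L && length(fits) > 1L) {
    cum_lookup <- cum[[lk]] + build_time
    crossover <- vapply(setdiff(seq_along(fits), lk), function(i) {
      crossover_iteration(cum_lookup, cum[[i]])
    }, numeric(1))
    names(crossover) <- names(fits)[setdiff(seq_along(fits), lk)]
  }
  structure(list(summary = summary, cumulative = cum,
                 build_time = build_time, crossover = crossover),
            class = "cmp_timing")
}

#' @rdname timing_report
#' @param cum_a,cum_b Cumulative-time curves (same length); returns the
#'   first index at which `cum_a <= cum_b`, or `NA`.
#' @export
crossover_iteration <- function(cum_a, cum_b) {
  stopifnot(length(cum_a) == length(cum_b))
  i <- which(cum_a <= cum_b)
  if (length(i) == 0L) NA_real_ else as.numeric(i[1L])
}

#' @export
print.cmp_timing <- function(x, ...) {
  print(x$summary)
  if (!is.null(x$crossover)) {
    cat("look-up crossover (incl. build time of", x$build_time, "s):\n")
    print(x$crossover)
  }
  invisible(x)
}
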