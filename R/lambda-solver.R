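#' Solve the MPCMP mean constraint for the rate parameter
#'
#' The mean-parameterised CMP model is indexed by its mean `mu`, but the
#' pmf needs the rate `lambda`.  `lambda(mu, nu)` is the unique root of the
#' mean constraint (the truncated mean is strictly increasing in
#' `log lambda`), obtainable three ways:
#'
#' * `"bisection"`: hybrid bisection/Newton on `log lambda`.  The bracket
#'   starts at `log mu` (exact at `nu = 1`) and expands geometrically by
#'   `log 2` until the constraint changes sign; Newton steps are taken once
#'   bracketed and fall back to bisection when they exit the bracket.
#' * `"polynomial"`: the unique positive real root of the degree-`k`
#'   polynomial `sum (r - mu) lambda^r / (r!)^nu` (a single sign change in
#'   the coefficients, so by Descartes' rule of signs there is exactly one
#'   positive real root), extracted from companion-matrix eigenvalues of
#'   the log-space-scaled coefficients.
#' * `"lookup"`: bilinear interpolation of a pre-computed table (see
#'   [build_lookup_table()]); `log G` is always recomputed from the
#'   returned `log lambda`.
#'
#' All three are vectorised over `mu` (and `nu`).
#'
#' @param mu Positive mean(s).
#' @param nu Non-negative dispersion(s); scalar or same length as `mu`.
#' @param method One of `"bisection"`, `"polynomial"`, `"lookup"`.
#' @param trunc Truncation policy; defaults to
#'   `trunc_series(max(60, ceiling(2 * max(mu))))`.
#' @param tol Bisection tolerance on `log lambda` (default `1e-10`).
#' @param table A `cmp_lookup` table, required for `method = "lookup"`.
#' @param k Polynomial degree for `method = "polynomial"`; defaults to the
#'   truncation `k`.
#' @return A list with numeric vectors `log_lambda` and `log_G`.
#' @examples
#' solve_lambda(7, 1)$log_lambda                     # log(7): Poisson
#' exp(solve_lambda(2, 0)$log_lambda)                # 2/3: geometric
#' @export
solve_lambda <- function(mu, nu, method = c("bisection", "polynomial", "lookup"),
                         trunc = NULL, tol = 1e-10, table = NULL, k = NULL) {
  method <- match.arg(method)
  switch(method,
    bisection = solve_lambda_bisection(mu, nu, trunc = trunc, tol = tol),
    polynomial = solve_lambda_polynomial(mu, nu, k = k, trunc = trunc),
    lookup = {
      if (is.null(table))
        stop("method = \"lookup\" requires a `table` (see build_lookup_table)",
             call. = FALSE)
      trunc <- if (is.null(trunc)) trunc_series(table$trunc_k) else trunc
      ll <- lookup_log_lambda(table, mu, nu)
      list(log_lambda = as.numeric(ll),
           log_G = .cpp_cmp_logG(as.numeric(ll), as.numeric(nu), trunc$k))
    })
}

#' @rdname solve_lambda
#' @export
solve_lambda_bisection <- function(mu, nu, trunc = NULL, tol = 1e-10) {
  stopifnot(all(mu > 0), all(nu >= 0), tol > 0)
  trunc <- as_trunc(trunc, mu)
  out <- .cpp_solve_bisection(as.numeric(mu), as.numeric(nu), trunc$k, tol)
  if (anyNA(out$log_lambda)) {
    bad <- which(is.na(out$log_lambda))[1L]
    stop(sprintf(
      "rate solver failed to bracket the mean constraint at mu = %g, nu = %g (k = %d)",
      mu[bad], rep_len(nu, length(mu))[bad], trunc$k), call. = FALSE)
  }
  if (trunc$mode == "series" && any(nu == 0)) {
    nuv <- rep_len(nu, length(mu))
    if (any(out$log_lambda[nuv == 0] >= 0))
      stop("nu = 0 with unbounded support requires lambda < 1: the series ",
           "diverges; use trunc_bound() for a genuinely bounded count",
           call. = FALSE)
  }
  out
}

#' @rdname solve_lambda
#' @export
solve_lambda_polynomial <- function(mu, nu, k = NULL, trunc = NULL) {
  stopifnot(all(mu > 0), all(nu >= 0))
  trunc <- as_trunc(trunc, mu)
  if (is.null(k)) k <- trunc$k
  k <- as.integer(k)
  if (k < ceiling(max(mu)) + 1L)
    stop("polynomial degree k must be at least ceiling(mu) + 1 so the ",
         "coefficient sequence has its single sign change", call. = FALSE)
  out <- .cpp_solve_polynomial(as.numeric(mu), as.numeric(nu), k)
  if (any(out$n_positive_roots == 0L) || anyNA(out$log_lambda)) {
    bad <- which(is.na(out$log_lambda))[1L]
    stop(sprintf(
      "no positive real root found at mu = %g, nu = %g (k too small or numerical breakdown)",
      mu[bad], rep_len(nu, length(mu))[bad]), call. = FALSE)
  }
  if (any(out$n_positive_roots > 1L))
    warning("multiple positive real roots survived the tolerance filter; ",
            "kept the one minimising the mean-constraint residual")
  list(log_lambda = out$log_lambda,
       log_G = .cpp_cmp_logG(out$log_lambda, as.numeric(nu), trunc$k))
}
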