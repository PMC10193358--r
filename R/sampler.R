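# Metropolis-within-Gibbs sampler for MPCMP regression.
#
# Update scheme per iteration: one multivariate-normal random-walk block for
# beta, one block for the free random effects theta (sum-to-zero enforced by
# reparameterisation), and a scalar normal random walk on each
# log-dispersion coefficient gamma_j.  Every update draws its proposal noise
# and its uniform accept variate unconditionally, so the RNG stream consumed
# is identical whatever the rate solver: chains run with different solvers
# share proposals exactly.

fit_k_default <- function(data, table) {
  if (!is.null(data$support_bound)) return(data$support_bound)
  if (!is.null(table)) return(table$trunc_k)
  max(60L, as.integer(ceiling(6 * max(data$y))))
}

# Solve log lambda by the configured method; returns NA entries on failure
# (the sampler treats a failed solve as log-posterior -Inf, i.e. reject).
solver_fun <- function(method, table, k, tol = 1e-10) {
  force(k)
  switch(method,
    lookup = {
      if (is.null(table))
        stop("method = \"lookup\" requires a look-up table", call. = FALSE)
      function(mu, nu) {
        res <- .cpp_lookup_loglambda(table$values, table$mu_nodes,
                                     table$nu_nodes,
                                     table$grid$spacing == "log-mu",
                                     mu, nu)
        structure(res$log_lambda, n_extrapolated = res$n_extrapolated)
      }
    },
    bisection = function(mu, nu)
      .cpp_solve_bisection(mu, nu, k, tol)$log_lambda,
    polynomial = function(mu, nu) {
      out <- .cpp_solve_polynomial(mu, nu, k)
      out$log_lambda
    },
    stop("unknown solver method: ", method, call. = FALSE))
}

#' Conditional log-posteriors of the MPCMP regression blocks
#'
#' `log_cond_beta()` evaluates, up to an additive constant, the log
#' conditional posterior of the mean coefficients: the normal log-prior
#' plus `sum_i [ y_i log lambda_i - log G(lambda_i, nu_i) ]` with
#' `lambda_i` solving the mean constraint at
#' `mu_i = exp(x1_i' beta + theta_{g(i)} + offset_i)`.
#' `log_cond_gamma()` is the dispersion analogue and additionally carries
#' the data-dependent term `- sum_i nu_i log(y_i!)`.
#'
#' These are the quantities the sampler compares; they are exported for
#' diagnostics and testing.  A rate-solve failure returns `-Inf`.
#'
#' @param beta,gamma Coefficient vectors for the mean / dispersion models.
#' @param theta Optional random effects on the mean (length `m`).
#' @param data A [regression_data()] object.
#' @param prior A [prior_spec()] object.
#' @param method,table,k Rate solver configuration (see [mcmc_config()]).
#' @return Scalar log-density (up to a constant).
#' @export
log_cond_beta <- function(beta, gamma, data, prior = prior_spec(),
                          theta = NULL, method = "bisection", table = NULL,
                          k = NULL) {
  if (is.null(k)) k <- fit_k_default(data, table)
  sf <- solver_fun(method, table, k)
  mu <- mpcmp_mu(data, beta, theta)
  nu <- as.numeric(exp(data$X2 %*% gamma))
  ll <- sf(mu, nu)
  if (anyNA(ll)) return(-Inf)
  terms <- .cpp_loglik_terms(data$y, as.numeric(ll), nu, k)
  sum(dnorm_log_vec(beta, prior$beta_mean, prior$beta_var)) + sum(terms)
}

#' @rdname log_cond_beta
#' @export
log_cond_gamma <- function(gamma, beta, data, prior = prior_spec(),
                           theta = NULL, method = "bisection", table = NULL,
                           k = NULL) {
  if (is.null(k)) k <- fit_k_default(data, table)
  sf <- solver_fun(method, table, k)
  mu <- mpcmp_mu(data, beta, theta)
  nu <- as.numeric(exp(data$X2 %*% gamma))
  ll <- sf(mu, nu)
  if (anyNA(ll)) return(-Inf)
  terms <- .cpp_loglik_terms(data$y, as.numeric(ll), nu, k)
  sum(dnorm_log_vec(gamma, prior$gamma_mean, prior$gamma_var)) + sum(terms)
}

mpcmp_mu <- function(data, beta, theta = NULL) {
  eta <- as.numeric(data$X1 %*% beta)
  if (!is.null(theta) && !is.null(data$group)) eta <- eta + theta[data$group]
  if (!is.null(data$offset)) eta <- eta + data$offset
  exp(eta)
}

dnorm_log_vec <- function(x, mean, var) {
  mean <- rep_len(mean, length(x))
  var <- rep_len(var, length(x))
  -0.5 * (x - mean)^2 / var - 0.5 * log(2 * pi * var)
}

# Starting values and an initial proposal covariance from a Poisson GLM
# (equidispersion start); the group effects enter through sum contrasts so
# the intercept keeps the overall level.
poisson_start <- function(data) {
  X <- data$X1
  m <- data$m
  if (m > 0L) {
    G <- matrix(0, data$n, m - 1L)
    for (j in seq_len(m - 1L)) G[, j] <- (data$group == j) - (data$group == m)
    X <- cbind(X, G)
  }
  off <- if (is.null(data$offset)) rep(0, data$n) else data$offset
  fit <- suppressWarnings(glm.fit(X, data$y, family = poisson(),
                                  offset = off))
  co <- fit$coefficients
  co[!is.finite(co)] <- 0
  w <- pmax(fit$weights, 1e-8)
  XtWX <- crossprod(X * sqrt(w))
  V <- tryCatch(solve(XtWX), error = function(e) diag(1e-2, ncol(X)))
  list(beta = co[seq_len(data$p)],
       theta_free = if (m > 0L) co[data$p + seq_len(m - 1L)] else numeric(0),
       V_beta = V[seq_len(data$p), seq_len(data$p), drop = FALSE],
       V_theta = if (m > 0L)
         V[data$p + seq_len(m - 1L), data$p + seq_len(m - 1L), drop = FALSE]
       else matrix(0, 0, 0))
}

chol_safe <- function(V) {
  V <- (V + t(V)) / 2
  out <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(out)) out <- chol(V + diag(1e-8 + abs(min(eigen(V,
    symmetric = TRUE, only.values = TRUE)$values)), nrow(V)))
  out
}

#' Fit an MPCMP regression by Metropolis-within-Gibbs
#'
#' Log-linear models for the mean (`X1`, plus optional individual random
#' effects `theta`) and the dispersion (`X2`).  See [mcmc_config()] for the
#' update scheme, adaptation and solver plumbing, and
#' [posterior_summary()] / [importance_ratios()] for what to do with the
#' result.
#'
#' @param data A [regression_data()] object.
#' @param prior A [prior_spec()]; defaults to vague priors.
#' @param config An [mcmc_config()].
#' @param table A `cmp_lookup` table (required when
#'   `config$method = "lookup"`).
#' @return An `mpcmp_fit` object: matrices of retained draws (`beta`
#'   `K x p`, `gamma` `K x q`, `theta` `K x m`), per-block acceptance
#'   rates, a per-iteration wall-time trace, the solve-failure and
#'   extrapolation counts, and the config echo.  With `chains > 1`, the
#'   per-chain fits are in `$chain_fits`, draws are stacked, and split
#'   R-hat per parameter is in `$rhat`.
#' @examples
#' sim <- simulate_scenario("I", seed = 1, n = 50)
#' fit <- fit_mpcmp(sim$data, config = mcmc_config(200, warmup = 100,
#'                                                 method = "bisection"))
#' posterior_summary(fit)[1:3, ]
#' @export
fit_mpcmp <- function(data, prior = prior_spec(), config = mcmc_config(),
                      table = NULL) {
  stopifnot(inherits(data, "regression_data"), inherits(prior, "cmp_prior"),
            inherits(config, "cmp_mcmc_config"))
  if (config$chains > 1L) {
    fits <- lapply(seq_len(config$chains), function(ch) {
      cfg <- config
      cfg$seed <- config$seed + ch - 1L
      cfg$chains <- 1L
      fit_mpcmp(data, prior, cfg, table)
    })
    out <- fits[[1L]]
    out$beta <- do.call(rbind, lapply(fits, `[[`, "beta"))
    out$gamma <- do.call(rbind, lapply(fits, `[[`, "gamma"))
    if (!is.null(out$theta))
      out$theta <- do.call(rbind, lapply(fits, `[[`, "theta"))
    out$chain_fits <- fits
    out$rhat <- {
      draws <- cbind(out$beta, out$gamma, out$theta)
      kk <- nrow(fits[[1L]]$beta)
      apply(draws, 2, function(v)
        rhat_split(matrix(v, nrow = kk)))
    }
    return(out)
  }
  run_mwg_chain(data, prior, config, table)
}

run_mwg_chain <- function(data, prior, config, table) {
  y <- data$y
  n <- data$n; p <- data$p; q <- data$q; m <- data$m
  k <- if (is.null(config$k)) fit_k_default(data, table) else config$k
  if (any(y > k))
    stop("responses exceed the series truncation k = ", k, call. = FALSE)
  sf <- solver_fun(config$method, table, k)
  set.seed(config$seed)

  st <- poisson_start(data)
  beta <- st$beta
  theta_free <- st$theta_free
  use_theta <- m > 0L
  free_m <- if (use_theta) (if (config$sum_to_zero) m - 1L else m) else 0L
  if (use_theta && !config$sum_to_zero) theta_free <- c(st$theta_free, 0)[seq_len(m)]
  gamma <- rep(0, q)

  expand_theta <- function(tf) {
    if (!use_theta) return(NULL)
    if (config$sum_to_zero) c(tf, -sum(tf)) else tf
  }
  theta <- expand_theta(theta_free)

  L_beta <- chol_safe(st$V_beta)
  L_theta <- if (free_m > 0L) chol_safe(st$V_theta[seq_len(free_m),
                                                   seq_len(free_m),
                                                   drop = FALSE])
             else matrix(0, 0, 0)
  s_beta <- 2.38 / sqrt(p)
  s_theta <- if (free_m > 0L) 2.38 / sqrt(free_m) else 1
  s_gamma <- rep(0.2, q)
  target_beta <- if (p > 1L) 0.234 else 0.44
  target_theta <- 0.234

  prior_beta <- function(b) sum(dnorm_log_vec(b, prior$beta_mean, prior$beta_var))
  prior_gamma <- function(g) dnorm_log_vec(g, prior$gamma_mean, prior$gamma_var)
  prior_theta <- function(th) if (use_theta)
    sum(-0.5 * th^2 / prior$theta_var) else 0

  gamma_obs <- lapply(seq_len(q), function(j) which(data$X2[, j] != 0))

  nu <- as.numeric(exp(data$X2 %*% gamma))
  mu <- mpcmp_mu(data, beta, theta)
  n_fail <- 0L; n_extra <- 0L
  eval_terms <- function(idx, mu_i, nu_i) {
    ll <- sf(mu_i, nu_i)
    ne <- attr(ll, "n_extrapolated")
    if (!is.null(ne)) n_extra <<- n_extra + ne
    if (anyNA(ll)) { n_fail <<- n_fail + 1L; return(NULL) }
    .cpp_loglik_terms(y[idx], as.numeric(ll), nu_i, k)
  }
  cur_terms <- eval_terms(seq_len(n), mu, nu)
  if (is.null(cur_terms))
    stop("rate solver failed at the starting values (mu in [",
         signif(min(mu), 3), ", ", signif(max(mu), 3), "])", call. = FALSE)

  total_iter <- config$warmup + config$iterations
  keep <- seq(config$warmup + config$thin, total_iter, by = config$thin)
  K <- length(keep)
  draw_beta <- matrix(NA_real_, K, p,
                      dimnames = list(NULL, colnames(data$X1)))
  draw_gamma <- matrix(NA_real_, K, q,
                       dimnames = list(NULL, colnames(data$X2)))
  draw_theta <- if (use_theta)
    matrix(NA_real_, K, m, dimnames = list(NULL, paste0("theta[", 1:m, "]")))
  else NULL
  iter_time <- numeric(total_iter)
  acc <- c(beta = 0, theta = 0)
  acc_gamma <- rep(0, q)
  n_acc_window <- max(1L, total_iter - config$warmup)
  ki <- 0L

  for (it in seq_len(total_iter)) {
    t0 <- proc.time()[3L]
    adapting <- config$adapt && it <= config$warmup
    gain <- it^-0.6

    # --- beta block ---
    z <- rnorm(p); u <- runif(1)
    beta_prop <- beta + s_beta * drop(crossprod(L_beta, z))
    mu_prop <- mpcmp_mu(data, beta_prop, theta)
    new_terms <- eval_terms(seq_len(n), mu_prop, nu)
    lr <- if (is.null(new_terms)) -Inf else
      sum(new_terms) - sum(cur_terms) + prior_beta(beta_prop) - prior_beta(beta)
    if (is.nan(lr))
      stop("NaN in the beta conditional at iteration ", it,
           "; state: beta = ", paste(signif(beta, 4), collapse = ", "))
    if (log(u) < lr) {
      beta <- beta_prop; mu <- mu_prop; cur_terms <- new_terms
      if (it > config$warmup) acc["beta"] <- acc["beta"] + 1
    }
    if (adapting)
      s_beta <- exp(log(s_beta) + gain * (min(1, exp(lr)) - target_beta))

    # --- theta block ---
    if (free_m > 0L) {
      z <- rnorm(free_m); u <- runif(1)
      tf_prop <- theta_free + s_theta * drop(crossprod(L_theta, z))
      theta_prop <- expand_theta(tf_prop)
      mu_prop <- mpcmp_mu(data, beta, theta_prop)
      new_terms <- eval_terms(seq_len(n), mu_prop, nu)
      lr <- if (is.null(new_terms)) -Inf else
        sum(new_terms) - sum(cur_terms) +
          prior_theta(theta_prop) - prior_theta(theta)
      if (is.nan(lr))
        stop("NaN in the theta conditional at iteration ", it)
      if (log(u) < lr) {
        theta_free <- tf_prop; theta <- theta_prop
        mu <- mu_prop; cur_terms <- new_terms
        if (it > config$warmup) acc["theta"] <- acc["theta"] + 1
      }
      if (adapting)
        s_theta <- exp(log(s_theta) + gain * (min(1, exp(lr)) - target_theta))
    }

    # --- gamma components (scalar random walks on the log-dispersion) ---
    for (j in seq_len(q)) {
      z <- rnorm(1); u <- runif(1)
      gj_prop <- gamma[j] + s_gamma[j] * z
      idx <- gamma_obs[[j]]
      gamma_prop <- gamma; gamma_prop[j] <- gj_prop
      nu_prop_idx <- as.numeric(exp(data$X2[idx, , drop = FALSE] %*% gamma_prop))
      new_terms <- eval_terms(idx, mu[idx], nu_prop_idx)
      lr <- if (is.null(new_terms)) -Inf else
        sum(new_terms) - sum(cur_terms[idx]) +
          dnorm_log_vec(gj_prop, rep_len(prior$gamma_mean, q)[j],
                        rep_len(prior$gamma_var, q)[j]) -
          dnorm_log_vec(gamma[j], rep_len(prior$gamma_mean, q)[j],
                        rep_len(prior$gamma_var, q)[j])
      if (is.nan(lr))
        stop("NaN in the gamma conditional at iteration ", it)
      if (log(u) < lr) {
        gamma <- gamma_prop
        nu[idx] <- nu_prop_idx
        cur_terms[idx] <- new_terms
        if (it > config$warmup) acc_gamma[j] <- acc_gamma[j] + 1
      }
      if (adapting)
        s_gamma[j] <- exp(log(s_gamma[j]) + gain * (min(1, exp(lr)) - 0.44))
    }

    if (it > config$warmup && ((it - config$warmup) %% config$thin == 0L)) {
      ki <- ki + 1L
      draw_beta[ki, ] <- beta
      draw_gamma[ki, ] <- gamma
      if (use_theta) draw_theta[ki, ] <- theta
    }
    iter_time[it] <- proc.time()[3L] - t0
  }

  structure(list(
    beta = draw_beta, gamma = draw_gamma, theta = draw_theta,
    accept = c(beta = unname(acc["beta"]) / n_acc_window,
               theta = if (free_m > 0L) unname(acc["theta"]) / n_acc_window
                       else NA_real_),
    accept_gamma = acc_gamma / n_acc_window,
    iter_time = iter_time,
    n_solver_failures = n_fail,
    n_extrapolated = n_extra,
    proposal_scales = list(beta = s_beta, theta = s_theta, gamma = s_gamma),
    k = k, method = config$method, config = config, prior = prior,
    table = table), class = "mpcmp_fit")
}

#' @export
print.mpcmp_fit <- function(x, ...) {
  cat(sprintf(
    "<mpcmp_fit> %d retained draws (%s solver, k = %d)\n",
    nrow(x$beta), x$method, x$k))
  cat(sprintf("  acceptance: beta %.2f%s; mean iter time %.4gs\n",
              x$accept["beta"],
              if (!is.na(x$accept["theta"]))
                sprintf(", theta %.2f", x$accept["theta"]) else "",
              mean(x$iter_time)))
  if (x$n_extrapolated > 0)
    cat("  note:", x$n_extrapolated, "look-up queries were extrapolated\n")
  invisible(x)
}

#' Highest-density interval of a sample
#'
#' Shortest interval containing `level` mass of the sorted draws.
#'
#' @param x Numeric draws.
#' @param level Mass to cover (default 0.95).
#' @return Length-2 vector `c(lower, upper)`.
#' @export
hdi <- function(x, level = 0.95) {
  stopifnot(level > 0, level < 1)
  xs <- sort(x)
  n <- length(xs)
  w <- ceiling(level * n)
  if (w >= n) return(c(xs[1L], xs[n]))
  widths <- xs[(w + 1L):n] - xs[1:(n - w)]
  i <- which.min(widths)
  c(xs[i], xs[i + w])
}

#' Posterior summary table
#'
#' Per-parameter posterior mean, SD, batch-means Monte-Carlo standard
#' error, and highest-density interval.
#'
#' @param fit An `mpcmp_fit`.
#' @param level HDI mass (default 0.95).
#' @return A data frame with one row per parameter.
#' @export
posterior_summary <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "mpcmp_fit"))
  draws <- cbind(fit$beta, fit$gamma, fit$theta)
  if (nrow(draws) < 100L)
    warning("fewer than 100 draws: summaries will be noisy")
  out <- data.frame(
    parameter = colnames(draws),
    mean = colMeans(draws),
    sd = apply(draws, 2, sd),
    mcse = apply(draws, 2, mcse_batch),
    row.names = NULL)
  h <- t(apply(draws, 2, hdi, level = level))
  out$hdi_lower <- h[, 1L]
  out$hdi_upper <- h[, 2L]
  out
}

#' Monte-Carlo standard error by batch means
#'
#' @param x Draws from a single chain.
#' @param n_batches Number of batches (default `floor(sqrt(length(x)))`).
#' @return Scalar MCSE of the sample mean.
#' @export
mcse_batch <- function(x, n_batches = NULL) {
  n <- length(x)
  if (is.null(n_batches)) n_batches <- max(2L, floor(sqrt(n)))
  b <- floor(n / n_batches)
  means <- vapply(seq_len(n_batches),
                  function(i) mean(x[((i - 1L) * b + 1L):(i * b)]), numeric(1))
  sd(means) / sqrt(n_batches)
}

# split R-hat on a K x chains matrix of draws
rhat_split <- function(mat) {
  K <- nrow(mat)
  half <- floor(K / 2)
  sub <- cbind(mat[1:half, , drop = FALSE],
               mat[(K - half + 1):K, , drop = FALSE])
  mns <- colMeans(sub)
  vars <- apply(sub, 2, stats::var)
  W <- mean(vars)
  B <- half * stats::var(mns)
  sqrt(((half - 1) / half * W + B / half) / W)
}
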