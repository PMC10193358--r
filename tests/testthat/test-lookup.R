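# Look-up table: build, query (interpolation/extrapolation), round-trip
# serialisation.

test_that("the nu = 1 column of a built table is log(mu)", {
  tab <- test_table()
  j <- which(abs(tab$nu_nodes - 1) < 1e-12)
  expect_length(j, 1L)
  expect_lt(max(abs(tab$values[, j] - log(tab$mu_nodes))), 1e-8)
})

test_that("tabulated log lambda is strictly increasing in mu and finite", {
  tab <- test_table()
  expect_true(all(is.finite(tab$values)))
  expect_true(all(apply(tab$values, 2, function(v) all(diff(v) > 0))))
})

test_that("parallel builds are identical to serial builds", {
  g <- lookup_grid(mu_min = 0.5, mu_max = 4, mu_step = 0.25,
                   nu_min = 0.5, nu_max = 2, nu_step = 0.25)
  t1 <- build_lookup_table(g, trunc_k = 64, workers = 1)
  t2 <- build_lookup_table(g, trunc_k = 64, workers = 3)
  expect_identical(t1$values, t2$values)
})

test_that("stored nodes match an independent re-solve", {
  tab <- test_table()
  set.seed(21)
  ii <- sample(length(tab$mu_nodes), 25)
  jj <- sample(length(tab$nu_nodes), 25)
  for (s in seq_along(ii)) {
    expect_equal(tab$values[ii[s], jj[s]],
                 bisect_oracle(tab$mu_nodes[ii[s]], tab$nu_nodes[jj[s]],
                               k = tab$trunc_k),
                 tolerance = 1e-8)
  }
})

test_that("node queries are exact and edge queries reduce to 1-D interpolation", {
  tab <- test_table()
  expect_identical(lookup_log_lambda(tab, tab$mu_nodes[37], tab$nu_nodes[5]),
                   structure(tab$values[37, 5], n_extrapolated = 0L))
  # on a mu edge: linear in the nu weight only
  mu0 <- tab$mu_nodes[40]
  nu_q <- (tab$nu_nodes[6] + tab$nu_nodes[7]) / 2
  expect_equal(as.numeric(lookup_log_lambda(tab, mu0, nu_q)),
               (tab$values[40, 6] + tab$values[40, 7]) / 2, tolerance = 1e-12)
  # on a nu edge: weights on the log-mu scale
  nu0 <- tab$nu_nodes[6]
  m1 <- tab$mu_nodes[40]; m2 <- tab$mu_nodes[41]
  mu_q <- (m1 + m2) / 2
  w <- (log(mu_q) - log(m1)) / (log(m2) - log(m1))
  expect_equal(as.numeric(lookup_log_lambda(tab, mu_q, nu0)),
               (1 - w) * tab$values[40, 6] + w * tab$values[41, 6],
               tolerance = 1e-12)
})

test_that("interior interpolation error stays below the frozen bound", {
  tab <- test_table()  # 0.02 x 0.1 steps
  set.seed(8)
  mu <- exp(runif(500, log(0.05), log(15.5)))
  nu <- runif(500, 0.05, 3.9)
  ex <- solve_lambda_bisection(mu, nu, trunc_series(tab$trunc_k))$log_lambda
  err <- abs(lookup_log_lambda(tab, mu, nu) - ex)
  expect_lt(max(err), 3e-3)  # frozen from the oracle run for this grid
  # away from the nu -> 0 geometric corner the error is far smaller
  expect_lt(max(err[nu > 0.25]), 1e-3)
})

test_that("interpolated values are monotone in mu within cells", {
  tab <- test_table()
  mu <- seq(1.003, 1.497, by = 0.004)  # spans ~25 cells off-node
  ll <- lookup_log_lambda(tab, mu, 1.57)
  expect_true(all(diff(ll) > 0))
})

test_that("halving both grid steps shrinks the max error at least 3-fold", {
  gA <- lookup_grid(mu_min = 0.5, mu_max = 8, mu_step = 0.04,
                    nu_min = 0.25, nu_max = 3, nu_step = 0.2)
  gB <- lookup_grid(mu_min = 0.5, mu_max = 8, mu_step = 0.02,
                    nu_min = 0.25, nu_max = 3, nu_step = 0.1)
  tA <- build_lookup_table(gA, trunc_k = 64)
  tB <- build_lookup_table(gB, trunc_k = 64)
  set.seed(7)
  mu <- runif(300, 1, 7.5)
  nu <- runif(300, 0.35, 2.8)
  ex <- solve_lambda_bisection(mu, nu, trunc_series(64))$log_lambda
  eA <- max(abs(lookup_log_lambda(tA, mu, nu) - ex))
  eB <- max(abs(lookup_log_lambda(tB, mu, nu) - ex))
  expect_gte(eA / eB, 3)
})

test_that("extrapolation is continuous at the hull and tracks the Poisson line", {
  tab <- test_table()
  mu_max <- max(tab$mu_nodes)
  inside <- as.numeric(lookup_log_lambda(tab, mu_max - 1e-9, 1.5))
  outside <- as.numeric(lookup_log_lambda(tab, mu_max + 1e-9, 1.5,
                                          warn = FALSE))
  expect_equal(inside, outside, tolerance = 1e-6)
  # at nu = 1 log lambda is exactly linear in log mu, so extrapolation is
  # exact there up to truncation effects
  got <- lookup_log_lambda(tab, 1.2 * mu_max, 1, warn = FALSE)
  expect_equal(as.numeric(got), log(1.2 * mu_max), tolerance = 1e-4)
  expect_identical(attr(got, "n_extrapolated"), 1L)
})

test_that("extrapolation warns once per query call", {
  tab <- test_table()
  expect_warning(lookup_log_lambda(tab, 2 * max(tab$mu_nodes), 1.5),
                 "extrapolation")
  expect_silent(lookup_log_lambda(tab, 2, 1.5))
})

test_that("tables round-trip through the text format exactly", {
  g <- lookup_grid(mu_min = 0.5, mu_max = 3, mu_step = 0.5,
                   nu_min = 0.5, nu_max = 2, nu_step = 0.5)
  tab <- build_lookup_table(g, trunc_k = 64)
  path <- withr::local_tempfile(fileext = ".txt")
  write_lookup_table(tab, path)
  back <- read_lookup_table(path)
  expect_identical(back$values, tab$values)
  expect_identical(back$mu_nodes, tab$mu_nodes)
  expect_identical(back$nu_nodes, tab$nu_nodes)
  expect_identical(back$trunc_k, tab$trunc_k)
  expect_equal(back$grid, tab$grid)
})

test_that("a hand-written 2x2 table file parses into known values", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(
    "# mu_min=1", "# mu_max=2", "# mu_step=1",
    "# nu_min=0.5", "# nu_max=1.5", "# nu_step=1",
    "# spacing=linear-mu", "# trunc_k=60", "# version=test",
    "0.5 1.5",
    "1 -0.1 0.2",
    "2 0.5 0.8"), path)
  tab <- read_lookup_table(path)
  expect_identical(tab$values, rbind(c(-0.1, 0.2), c(0.5, 0.8)))
  expect_identical(tab$mu_nodes, c(1, 2))
  # interpolation midway: weights 0.5 in nu, log-scale in mu
  expect_equal(as.numeric(lookup_log_lambda(tab, 1, 1)), 0.05,
               tolerance = 1e-12)
})

test_that("malformed table files are rejected with a line number", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# mu_min=1", "# mu_max=2", "# mu_step=1", "# nu_min=0.5",
               "# nu_max=1.5", "# nu_step=1", "# spacing=linear-mu",
               "# trunc_k=60",
               "0.5 1.5",
               "1 -0.1 0.2",
               "2 0.5"), path)
  expect_error(read_lookup_table(path), "line 11")
  path2 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# mu_min=1", "0.5 1.5", "1 0 0"), path2)
  expect_error(read_lookup_table(path2), "header")
})
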