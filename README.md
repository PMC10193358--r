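# bidisperse

Bayesian regression for count data that are underdispersed,
overdispersed, or — at some hierarchical level — both at once
("bidispersed"), built on the mean-parameterised Conway–Maxwell–Poisson
(MPCMP) distribution with a fast pre-computed look-up table for its rate
parameter.  It is aimed at analysts fitting hierarchical count models
where Poisson is wrong in both directions at once (sports event counts
per official or player, parity data, stable-vs-volatile longitudinal
counts) and where exact doubly-intractable fitting is too slow to be
routine.

## The model

The CMP pmf with rate $\lambda > 0$ and dispersion $\nu \ge 0$ is

$$\Pr(Y = y \mid \lambda, \nu) = \frac{\lambda^y}{(y!)^{\nu}}
  \frac{1}{G(\lambda,\nu)}, \qquad
  G(\lambda,\nu) = \sum_{r=0}^{\infty} \frac{\lambda^r}{(r!)^{\nu}},$$

covering Poisson ($\nu = 1$), geometric ($\nu = 0$), underdispersion
($\nu > 1$) and overdispersion ($\nu < 1$).  The mean-parameterised form
replaces $\lambda$ by the solution $\lambda(\mu,\nu)$ of the mean
constraint $\sum_{r\ge0} (r - \mu)\lambda^r/(r!)^{\nu} = 0$, so that
log-linear regressions $\log\mu_i = x_{1i}^\top\beta + \theta_{g(i)}$
and $\log\nu_i = x_{2i}^\top\gamma$ carry the usual GLM interpretation.
Each posterior evaluation then needs $\lambda(\mu_i, \nu_i)$ for every
observation.  The package offers three interchangeable routes:

* **bisection** — hybrid bisection/Newton on the mean constraint (exact);
* **polynomial** — the unique positive real root of the degree-$k$
  coefficient polynomial, by companion-matrix eigenvalues (exact);
* **lookup** — bilinear interpolation of a pre-computed
  $(\mu,\nu) \mapsto \log\lambda$ grid (fast; accurate to a few
  $10^{-4}$ in $\log\lambda$ on the default grid).

A Metropolis-within-Gibbs sampler (`fit_mpcmp()`) updates $\beta$ and
the sum-to-zero random effects as blocks and each log-dispersion
component by a scalar random walk, with warmup-only Robbins–Monro
adaptation.  The importance-ratio diagnostic
$m_e = (\sum_t r_t)^2 / \sum_t r_t^2$ over $K$ retained draws
(`importance_ratios()`, `approx_ess()`) measures how much posterior the
look-up approximation loses: $m_e \approx K$ means "as good as exact".
See the methods vignette (`vignettes/mpcmp-lookup-methods.Rmd`) for the
full account.

## Worked example

Simulate the small underdispersed scenario (n = 150, ten-parameter mean
model, $\nu = 1.5$), build the default look-up table, fit with the
look-up solver, and check the approximation with $m_e$:

```r
library(bidisperse)

tab <- build_lookup_table()          # mu 0.01..32 step 0.01; nu 0..10 step 0.05
sim <- simulate_scenario("I", seed = 1)
sim$data
#> <regression_data> n = 150, p = 10 (mean), q = 1 (dispersion)

fit <- fit_mpcmp(sim$data, prior_spec(),
                 mcmc_config(iterations = 2000, warmup = 1000, seed = 2,
                             method = "lookup"), table = tab)
fit
#> <mpcmp_fit> 2000 retained draws (lookup solver, k = 64)
#>   acceptance: beta 0.23; mean iter time 0.001063s

posterior_summary(fit)[c(1, 11), ]   # intercept and log-dispersion
#>      parameter    mean    sd  mcse hdi_lower hdi_upper
#> 1  (Intercept)  0.5043 0.190 0.020     0.114     0.826
#> 11 (Intercept) -0.0393 0.213 0.012    -0.480     0.320

importance_ratios(fit, sim$data, reference = "bisection", K = 1000)
#> <cmp_importance> m_e = 1000.0 of K = 1000 (reference: bisection)
```

The first summary row is the mean-model intercept (generating value
0.7); the second is the scalar log-dispersion $\log\nu$ (generating
value $\log 1.5 \approx 0.41$; this particular dataset happens to look
nearly equidispersed — across seeds the posterior centres on the truth).
The final line is the headline diagnostic: of 1000 retained draws from
the look-up chain, effectively 1000 are "exact" — the interpolated rates
are statistically indistinguishable from solving the mean constraint at
every iteration, while costing a fraction of the time per iteration
(`timing_report()` compares solvers and reports the crossover iteration
at which the table build has paid for itself).

A command-line interface wrapping the same functions is installed at
`inst/cli/bidisperse` (subcommands `build-table`, `simulate`, `fit`,
`diagnose`).

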