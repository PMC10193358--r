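---
title: "Mean-parameterised CMP regression with a rate look-up table: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mean-parameterised CMP regression with a rate look-up table: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bidisperse)
```

## The problem: counts that are under-, over-, or both-dispersed

Poisson regression forces the variance of a count response to equal its
mean.  Real count data rarely oblige: overdispersion (variance above the
mean) is routine and is usually handled with a negative binomial model,
while underdispersion (variance below the mean) has far fewer practical
options.  Hierarchical data often show *bidispersion* — some individuals
(referees, bowlers, patients) are overdispersed while others are
underdispersed within the same dataset — and then neither Poisson nor
negative binomial is tenable in either direction.

The Conway–Maxwell–Poisson (CMP) distribution spans the whole dispersion
spectrum.  Its pmf for rate $\lambda > 0$ and dispersion $\nu \ge 0$ is

$$\Pr(Y = y \mid \lambda, \nu) = \frac{\lambda^y}{(y!)^\nu}\,
  \frac{1}{G(\lambda, \nu)}, \qquad
  G(\lambda, \nu) = \sum_{r=0}^{\infty} \frac{\lambda^r}{(r!)^\nu},$$

with $\nu = 1$ giving Poisson, $\nu = 0$ geometric, $\nu > 1$
underdispersion and $\nu < 1$ overdispersion.  Two difficulties block
routine use: the normalising constant $G$ has no closed form (the model
is *doubly intractable* in a Bayesian analysis), and $\lambda$ is not the
mean, so regression coefficients on $\log\lambda$ have no direct
interpretation.

The *mean-parameterised* CMP (MPCMP) fixes the second problem by
indexing the distribution by its mean $\mu$, defined implicitly through

$$\mu = \sum_{r=0}^{\infty} \frac{r\,\lambda^r}{(r!)^\nu\,G(\lambda,\nu)}
 \quad\Longleftrightarrow\quad
 \sum_{r=0}^{\infty} (r - \mu)\,\frac{\lambda^r}{(r!)^\nu} = 0 ,$$

at the cost of having to *invert* this mean constraint for
$\lambda(\mu, \nu)$ every time the pmf is evaluated.  In an MCMC fit with
$n$ observations that inversion happens $O(n)$ times per iteration, and
it is the computational bottleneck this package removes.

## Truncation of the infinite series

All series are evaluated as finite sums of $k + 1$ terms, in log space
with log-sum-exp (`trunc_series()`, `trunc_bound()`):

* **Series truncation** (`trunc_series`): a numerical cut-off.  The
  default is $k = \max(60, \lceil 2\mu \rceil)$ — about twice the largest
  mean in play — which is ample for the low-count, moderate-dispersion
  regimes the model targets; the tests verify that $k = 60$ versus
  $k = 90$ changes nothing at the $10^{-8}$ level for $\mu \le 12$,
  $\nu \ge 0.5$.  At the extreme corner (large $\mu$ with small $\nu$)
  the truncated model is what the package computes, consistently across
  all solvers, so comparisons remain exact even where the tail is not
  negligible.
* **Hard support bound** (`trunc_bound`): the counts genuinely cannot
  exceed $y_\tau$ (e.g. ten wickets per innings), the support is exactly
  $\{0,\dots,k\}$ with $k = y_\tau$, and the series is finite by
  construction rather than by approximation.

$\mu = 0$ is rejected as a degenerate point mass.  $\nu = 0$ under
series truncation is accepted only when the solved $\lambda < 1$
(otherwise the untruncated geometric series diverges and the model is
meaningless; the solver raises an error instead of silently truncating).

## Three routes to the rate

`solve_lambda()` dispatches between:

1. **Hybrid bisection/Newton** (`"bisection"`): the truncated mean is
   strictly increasing in $\log\lambda$, so the root is unique.  The
   bracket starts at $\log\mu$ (exact at $\nu = 1$) and expands by
   $\pm\log 2$ until the constraint changes sign; Newton steps (the
   derivative of the mean in $\log\lambda$ is the variance) are used
   once bracketed and fall back to bisection if they exit the bracket.
   Default tolerance: $10^{-10}$ on $\log\lambda$ (the tolerance is a
   package choice; a looser one would be invisible at the accuracy
   levels discussed below).
2. **Polynomial roots** (`"polynomial"`): $\sum_{r=0}^k (r-\mu)
   \lambda^r/(r!)^\nu$ has a single coefficient sign change, so by
   Descartes' rule of signs exactly one positive real root.  The
   coefficients are built in log space with explicit signs, scaled by
   the largest magnitude, and all roots extracted as companion-matrix
   eigenvalues.  A root is accepted as "real positive" when
   $|\mathrm{Im}| < 10^{-8}(1 + |\mathrm{Re}|)$ and $\mathrm{Re} > 0$;
   if several survive the filter the one minimising the mean-constraint
   residual is kept, with a warning.  Because the eigenvalue cost is
   cubic in the degree, trailing coefficients that cannot contribute
   more than $e^{-30}$ of the dominant one at any $\lambda$ up to a
   crude closed-form root bound are dropped first; a residual check
   falls back to the full degree when the trim was too aggressive.
   The two exact solvers agree to better than $10^{-7}$ relative across
   the tested $(\mu,\nu)$ ranges — this cross-check is the module's
   primary oracle, with base R's Jenkins–Traub `polyroot` as a further
   independent reference in the tests.
3. **Look-up table** (`"lookup"`): described next.  Whatever the route,
   $\log G$ is always recomputed from the returned $\log\lambda$.

## The look-up table

`build_lookup_table()` solves the mean constraint once per node of a
$(\mu, \nu)$ grid and stores $\log\lambda$.  The default grid uses a
step of 0.01 for $\mu$ from 0.01 to 32 — a ceiling over three times the
largest count the bundled scenarios can produce — and $\nu$ from 0 to
10.  The $\nu$ step defaults to 0.05, a package choice that keeps the
$\nu$-direction interpolation error well below the $\mu$-direction error
while keeping the table at 643K nodes (it builds in seconds and a table
file stays a few tens of MB as text).  Queries use bilinear
interpolation over the four surrounding nodes with the $\mu$ weight on
the $\log\mu$ scale,

$$\Delta_\mu = \frac{\log\mu - \log\mu_1}{\log\mu_2 - \log\mu_1},
  \qquad \Delta_\nu = \frac{\nu - \nu_1}{\nu_2 - \nu_1},$$

and *extrapolation* — the same bilinear form on the nearest boundary
cell with weights outside $[0,1]$ — for queries outside the hull.
Extrapolation is a safeguard, not a working regime: it is flagged (once
per call, and counted in fits) and none of the bundled scenarios
trigger it at the retained draws.

On the default grid the worst interpolation error over random interior
queries is a few times $10^{-4}$ in $\log\lambda$ (the exact bound is
frozen in the tests from an oracle run against the bisection solver),
and halving both steps shrinks it at least three-fold, as the quadratic
local truncation error of bilinear interpolation predicts.  One caveat
is intrinsic to the parameterisation: near $\nu = 0$ the mean is
extremely sensitive to $\lambda$ (in the geometric limit
$\mu = \lambda/(1-\lambda)$ diverges as $\lambda \to 1$), so a fixed
error in $\log\lambda$ translates into a relative mean error an order
of magnitude larger in the corner $\nu < 0.1$.  The deeply
overdispersed corner is also where the model itself is at the edge of
its geometric overdispersion limit.

The table serialises as a plain-text file (`write_lookup_table()`):
`#`-header `key=value` lines, a row of $\nu$ nodes, then one row per
$\mu$ node, all at 17 significant digits so that the round trip is
value-exact.  A hash-table keyed on $(\mu,\nu)$ pairs was deliberately
not used: a dense matrix with direct index arithmetic is both simpler
and faster per query, and the grid hull plus extrapolation covers the
open-ended domain a hash table would otherwise offer.

## The Bayesian regression model and its sampler

`fit_mpcmp()` fits log-linear models for both components,

$$\log\mu_i = x_{1i}^\top\beta + \theta_{g(i)} + \text{offset}_i,
  \qquad \log\nu_i = x_{2i}^\top\gamma,$$

with optional individual random effects $\theta$ on the mean and, via an
indicator design for $x_{2i}$, individual dispersions
$\alpha_i = \log\nu_i$.  Priors are independent normals throughout
(`prior_spec()`): vague $N(0, 10^5)$ defaults for $\beta$ and a scalar
log-dispersion, $N(0, 0.25)$ as the conventional choice for
individual-level log-dispersions (centring them on equidispersion), and
$N(0, 0.5\log 2)$ for the random effects, which treats a doubling or
halving of the rate as a tail event.

A Metropolis-within-Gibbs scheme updates, per iteration:

* $\beta$ as one multivariate-normal random-walk block;
* the free random effects as a second block, with the sum-to-zero
  identifiability constraint enforced by *reparameterisation* — $m - 1$
  free components with $\theta_m = -\sum_{i<m}\theta_i$ — so the
  constraint is exact in every draw rather than imposed by post-hoc
  centring;
* each $\gamma_j$ by a scalar normal random walk on the log-dispersion
  scale, evaluating only the observations its design column touches.

Starting values and the initial $\beta$/$\theta$ proposal covariances
come from a Poisson GLM (an equidispersion start) rather than from an
external MPCMP maximum-likelihood fit; Robbins–Monro adaptation of the
proposal scales during warmup targets acceptance 0.234 for blocks and
0.44 for scalars, and is frozen afterwards so detailed balance holds for
every retained draw.  The tests verify the resulting chain against a
dense grid evaluation of a small posterior (total-variation distance
below 0.05).

Two contracts matter for the solver comparisons: every update draws its
proposal noise and uniform accept variate unconditionally, so the RNG
stream is identical whatever the rate solver (chains run with different
solvers share proposals exactly — the tests assert the post-fit RNG
state is identical); and a rate-solve failure during a proposal is
treated as log-posterior $-\infty$ (reject) rather than an abort, while
a NaN aborts loudly with state information.  The per-iteration wall time
is recorded and summarised by `timing_report()`, including the iteration
at which the cumulative look-up cost (table build included) undercuts an
exact-solver chain; timings are reported, never asserted, because they
are hardware-dependent.

`fit_mpcmp()` runs a single chain by default — every bundled analysis is
sized for a single core — but `chains = 4` runs independent seeded
chains sequentially and reports split R-hat as convergence plumbing.

## Quantifying the look-up approximation: $m_e$

Replacing $\lambda$ by its interpolant $\tilde\lambda$ changes the
posterior.  The package quantifies the damage with importance ratios
between the exact and approximate unnormalised posteriors at the
retained draws,

$$r(\beta,\gamma) = \frac{\pi(\beta,\gamma\mid y)}
  {\tilde\pi(\beta,\gamma\mid y)}, \qquad
  m_e = \frac{\left(\sum_{t=1}^K r_t\right)^2}{\sum_{t=1}^K r_t^2},$$

with the exact rate from either the bisection or the polynomial solver
(`importance_ratios()`).  Priors and the $\nu\log y!$ term cancel in the
ratio; the log-ratios are stabilised by subtracting their maximum before
exponentiation, which is exact because $m_e$ is scale-invariant.  $m_e$
lies in $[1, K]$, equals $K$ iff all ratios are equal, and reads as "the
number of effectively exact draws among $K$": $m_e$ near $K = 1000$
means the look-up chain is essentially indistinguishable from an
exact-solver chain.  The $K$ draws default to the last 1000 retained —
a contiguous post-warmup window, not a thinned one, matching how the
diagnostic is meant to be read.  This is *not* the autocorrelation-based
MCMC effective sample size; it measures the approximation error of the
table, not the mixing of the chain.

## What the scenario generators emulate

`simulate_scenario()` reproduces three designs that mirror the data
regimes the model targets:

* **I** (small, underdispersed): $n = 150$, a ten-parameter mean model
  (five Bernoulli(0.5) covariates, one standard normal, two
  lognormal(0,1) of which one also enters squared), scalar $\nu = 1.5$.
  The design fixes the covariate laws and dispersion but not the
  coefficients; the frozen defaults were drawn once from $N(0, 0.3^2)$
  around an intercept of 0.7, with the slopes on the lognormal-derived
  columns shrunk (and the squared term made concave) so the heavy right
  tails keep the counts in the low single digits this regime represents.
  That is a documented package convention, not an estimate.
* **II** (moderate, bidispersed): $n = 2000$ from $m = 20$ individuals
  × 100 observations, two binaries plus interaction,
  $\beta = (1.00, -0.10, -0.20, 0.10)$, individual effects $\theta$ the
  arithmetic sequence $-0.475, \dots, 0.475$, and dispersions 0.8 for
  the first ten individuals, 1.25 for the rest.
* **III** (large, dispersion gradient): $n = 15000$ from $m = 100$
  individuals × 150 observations, four binaries,
  $\beta = (1, -0.10, 0.05, 0.10, 0.15)$, $\theta$ evenly spaced over
  the same range, and $\nu_i$ evenly spaced from 0.8 to 1.25 — the
  spacing is on the $\nu$ scale (not $\log\nu$), a documented choice.

The balanced designs are conveniences of the simulation, not
requirements of the model.  Counts are drawn by CDF inversion on the
truncated support, so everything is reproducible from a seed, and every
generator returns a truth record (including the generating
log-likelihood) so recovery tests need no external data.  What the
generators deliberately do not emulate: covariate measurement error,
missingness, unbalanced or informative cluster sizes, and temporal
structure within individuals.  Passing the bundled recovery tests
therefore demonstrates correctness of the machinery under the stated
designs, not robustness to those real-data complications.

## Problem sizes used in the checks

The test-suite and acceptance-script runs are sized for a desk-scale
single-core machine, as deliberate package choices: scenario I runs use
10 replicates with 500 warmup plus 1200–1500 retained iterations (the
diagnostic keeps the last $K = 1000$); scenario II uses full size in the
acceptance script and half size (20 × 50) in the tests; scenario III
runs at full size ($n = 15000$) in the acceptance script and scaled
down (40 × 75) in the tests.  The polynomial-reference diagnostic is
averaged over 4 replicates where the bisection reference uses 10 — its
replicate-to-replicate spread is an order of magnitude smaller than a
single effective-draw unit, so further replication adds nothing.
Parameter-recovery checks use 1000 warmup plus 4000–5000 iterations.

## Known limitations

* Overdispersion is capped at the geometric limit ($\nu = 0$): data more
  overdispersed than geometric cannot be represented at any $\lambda$.
* The table hull must be chosen with the data in mind ($\mu_{\max}$ of
  about three times the largest observable count works well);
  extrapolation far outside the hull degrades gracefully but is only a
  safeguard.
* The relative mean error of interpolated rates grows sharply as
  $\nu \to 0$ (see above); analyses living in $\nu < 0.1$ should use an
  exact solver or a finer $\nu$ grid near zero.
* Dispersion models beyond the log-linear form (e.g. covariates on
  $\nu$ with individual effects simultaneously) are expressible through
  `X2` but have not been exercised beyond the bundled designs.
* Gradient-based samplers (HMC/NUTS) are out of scope; the
  non-differentiable table interpolant and the per-observation root
  solves make them unattractive here.
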