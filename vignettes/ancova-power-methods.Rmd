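---
title: "Exact power and sample size for ANCOVA: methods and design choices"
author: "ancovapower"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact power and sample size for ANCOVA: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ancovapower)
```

## The model and the hypothesis

A one-way ANCOVA with `G` treatment groups and `P` covariates models the
response of subject `j` in group `i` as

    Y_ij = mu_i + sum_k X_kij beta_k + e_ij,    e_ij ~ N(0, sigma^2),

with common slopes `beta_k` across groups.  Treatment effects are statements
about the intercepts: a contrast matrix `C` (full row rank `c`, rows summing
to zero) encodes the hypothesis `C mu = 0`.  Because contrast rows sum to
zero, the same hypothesis can be written in terms of the adjusted group
means (group responses evaluated at the grand covariate mean), and the Wald
statistic

    W = (C mu_hat)' (C V C')^{-1} (C mu_hat) / (c * sigma2_hat)

is identical in the intercept form (with `V = D + Xbar' S_XX^{-1} Xbar`) and
the adjusted-mean form (with `V*`).  `fit_ancova()` computes both matrices
and `wald_test()` cross-checks the two quadratics on every call.  Under the
null, `W ~ F(c, nu)` with `nu = N_T - G - P`.

A note on the divisor: we scale the quadratic form by the contrast rank `c`,
not by `G - 1`.  For the omnibus contrast these coincide; for sub-maximal
contrasts only the divisor `c` is consistent with the `F(c, nu)` null law,
which the test suite verifies against the classical full-versus-reduced-model
F statistic and against the covariance matrix of a dummy-coded least-squares
fit.

## Why "exact" power differs from the conventional calculation

With the covariate values held fixed, `W` has a noncentral `F(c, nu,
Lambda)` law and power is a single noncentral-F tail probability
(`power_ncf()`).  But covariates in a planned study are not known in
advance: they are random.  When the covariates are i.i.d. multinormal, the
noncentrality parameter becomes the random variable

    Lambda = N_T * gamma^2 * B,     B ~ Beta((nu + 1)/2, P/2),

where `gamma^2 = (C mu)' (C Q C')^{-1} (C mu) / sigma^2` with
`Q = diag(1/q_i)` and allocation weights `q_i = N_i / N_T`.  Exact power is
the expectation of the fixed-covariate power over that Beta mixing law
(`power_ancova(method = "exact")`).  Neither the covariate mean vector nor
its covariance enters the law — only `P` does, through the Beta parameters —
which the Monte-Carlo engine verifies empirically.

The conventional (Cohen-style) calculation replaces `Lambda` by its upper
bound `Lambda_A = N_T * delta^2` (`method = "approx"`).  Since `0 < B < 1`,
that method always overstates power and understates the sample size, and the
gap widens with more covariates or larger effects.  The ANOVA reference
method (`power_anova()`) ignores the covariate degrees of freedom entirely
and uses `F(G - 1, N_T - G)` at `Lambda_O = (1 - rho^2) * N_T * delta^2`,
where `rho` is the response-covariate correlation; it is included because it
remains the most common planning shortcut.

For the omnibus contrast `gamma^2` reduces to `delta^2`, the
allocation-weighted variance of the intercepts over `sigma^2` — the ANCOVA
analogue of the ANOVA signal-to-noise ratio `f^2`.  `effect_size_delta2()`
is a convenience wrapper; the general-contrast path is the single code path,
and a property test confirms the two agree for random weights and
intercepts.

```{r}
e <- ancova_effect(mu = c(400, 450, 500), sigma2 = 7500)
d <- ancova_design(sizes = 16, G = 3, P = 1)
power_ancova(d, e, method = "exact")
power_ancova(d, e, method = "approx")
```

## Numerical evaluation of the Beta mixture

The mixing density is unbounded at `B -> 1` when `P = 1` (Beta with second
parameter 1/2), so naive quadrature against the density is fragile exactly
in the most common case.  We integrate in the quantile domain instead:
substituting `B = qbeta(u; a, b)` turns the expectation into
`integral_0^1 Psi(Gamma * qbeta(u)) du`, a smooth bounded integrand on
(0, 1), evaluated with Gauss–Legendre quadrature (`pracma::gaussLegendre`
nodes).  The default is 128 nodes; the result is accepted only when doubling
the node count changes it by less than `1e-6` (absolute), and node doubling
continues up to 4096 nodes before signalling non-convergence.  The test
suite checks the quadrature against a `1e6`-draw Beta Monte-Carlo average to
within `3e-4`, and spot cells against `stats::integrate` agree to seven
decimals.  Critical values come from the central-F inverse tail
(`stats::qf`) and noncentral tails from `stats::pf`; no series expansions
are re-implemented.

Powers are reported at full precision and rounded to 4 decimals only in
tabular output.  One benchmark cell (balanced `N_T = 63`, `P = 1`,
`delta^2 = 0.1684`) converges to 0.811559 — essentially on the rounding
boundary of the fourth decimal — so tests assert that cell to within one
unit of the fourth decimal rather than forcing a particular rounding;
`stats::integrate` and a large Beta Monte-Carlo average agree with the
quadrature to seven decimals there.

## Sample-size determination

`solve_sample_size()` scans the first-group size `N_1` upward in steps of 1
from the smallest feasible design (`N_i >= 2` for every group and at least
one error degree of freedom), with the other groups set by a priori
allocation ratios `N_i = ceiling(N_1 * r_i)`.  Ceiling rounding guarantees
the achieved power is at least the power of the un-rounded design; a linear
scan rather than bisection costs little at realistic magnitudes and is
immune to the small non-monotonicities that ratio rounding can create.  The
returned design is verified minimal in tests: power at `N_1 - 1` falls below
the target.  A search cap (`N_T = 1e6` by default) turns a null effect into
a clean divergence error.  The feasibility floor `N_i >= 2` is our choice;
it is the weakest floor under which every group contributes to the pooled
slope estimate.

The three methods can disagree materially.  At weak correlation the ANOVA
method needs fewer subjects than the exact method (`N_TA <= N_TO <= N_TE`);
at moderate-to-strong correlation the ordering of the last two reverses.
Both orderings are asserted on a grid in the test suite.

## The Monte-Carlo engine and what it does (not) show

`simulation_spec()` plus `empirical_power()` generate complete datasets from
the ANCOVA model — covariates from a configurable model, normal errors —
fit each one, and report the rejection rate of the Wald test at the
central-F critical value, alongside the three analytic powers.  Design
choices:

* **Streams.**  One master seed; replicate `i` uses the `i`-th
  L'Ecuyer-CMRG substream (`parallel::nextRNGStream`), so any replicate can
  be regenerated in isolation and results do not depend on execution order.
* **Slopes from a target correlation.**  Equal slopes are solved from
  `beta' Sigma beta / (beta' Sigma beta + sigma^2) = rho^2`
  (`solve_equal_slope()`; closed form `sqrt(rho^2 sigma^2 / ((1 - rho^2)
  P))` for identity covariance), so simulation scenarios are parameterized
  by the interpretable `rho` rather than raw slopes.
* **Non-normal families.**  Exponential, gamma, Laplace, lognormal, uniform
  and discrete-uniform covariates are supported for robustness checks.
  Their shape parameters are explicit defaults (exponential rate 1, gamma
  shape 2 / rate 1, Laplace scale 1, lognormal meanlog 0 / sdlog 1, uniform
  (0,1), discrete uniform on {1,...,5}) and each family is linearly
  standardized to zero mean and unit variance before slopes are applied, so
  the implied `rho` is comparable across families.
* **Degenerate draws.**  A replicate whose covariates yield a singular
  `S_XX` is redrawn within its stream and counted; more than 1%
  regenerations aborts the run.

The generator draws exactly the data-generating process the power formulas
assume: independent subjects, common slopes, homoscedastic normal errors,
covariates independent of treatment.  Passing validation therefore shows
internal correctness of the formulas under those assumptions — it says
nothing about heteroscedastic errors, group-specific slopes, measurement
error in covariates, or non-random treatment assignment, none of which the
package models.

Problem sizes: the bundled tests use 10,000 replicates for the two
headline simulation checks (type-I error, and the strong-correlation
`N_T = 18` power cell) and 1,000–1,500 replicates for auxiliary property
checks; a comparison of two Monte-Carlo estimates uses the combined
standard error of both.

## Known limitations

* Variance heterogeneity across groups is not modelled, in the formulas or
  the simulator.
* Treatment-by-covariate interactions (non-parallel slopes) are outside the
  model; `fit_ancova()` does not test for them.
* Missing data are rejected, not imputed.
* Multi-factor designs are supported only by encoding cell means through
  `mu` and a suitable contrast matrix; there is no factorial bookkeeping.
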