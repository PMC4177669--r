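---
title: "Optimal enzyme regulation under environmental uncertainty: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optimal enzyme regulation under environmental uncertainty: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regstrat)
```

## The decision problem

A cell regulates the expression level $E$ of a single metabolic enzyme in
response to the concentration $S$ of an environmental nutrient, which it can
only observe through a noisy readout $m$. The cell's instantaneous net payoff
is

$$P(E, S) = B(E, S) - C(E),$$

where the benefit $B$ is the rate of useful product from enzyme-catalyzed
metabolism and the cost $C$ is the burden of producing and maintaining the
enzyme. `regstrat` implements three benefit families — linear
($B = bES$, the unsaturated limit of Michaelis–Menten kinetics),
Michaelis–Menten ($B = bES/(K_M + S)$), and a power law in enzyme
($B = bSE^\gamma$) — and a power-law cost $C = cE^\alpha$. Fitness is taken to
be the *expected* payoff under the joint law of environment and measurement;
no variance or higher-moment sensitivity is modeled.

A *regulatory strategy* is a mapping from readout(s) to an enzyme level. The
package computes the optimal strategy in closed form for each combination of
payoff convexity, environmental prior, and measurement noise, and verifies
every closed form against brute-force oracles.

## Graded versus thresholded response

With perfect measurement the optimum at each $S$ maximizes $P(E, S)$ in $E$.
For cost and benefit that are power laws in $E$, the character of the optimum
is decided entirely by the relative convexity of cost and benefit:

* $\alpha > \gamma$ (cost strictly convex relative to benefit): a unique
  interior maximum exists and the optimal response is *graded*. For the
  linear benefit, $E^*(S) = (bS/c\alpha)^{1/(\alpha - 1)}$; for the general
  power law, $E^*(S) = (\gamma b S / \alpha c)^{1/(\alpha-\gamma)}$.
* $\alpha < \gamma$ (cost strictly concave relative to benefit): the payoff
  has no interior maximum on $E \ge 0$, so the optimum is *thresholding*:
  $E^* = E_{max}$ when $P(E_{max}, S) > 0$, i.e. when $S$ exceeds
  $S_t = (c/b)E_{max}^{\alpha-\gamma}$, and $E^* = 0$ otherwise. This case
  requires a finite maximal expression level $E_{max}$.
* $\alpha = \gamma$: the payoff is proportional to $E^\gamma$ and degenerates
  to boundary switching at the sign change of its coefficient ($S_t = c/b$).

```{r}
classify_response(alpha = 2, gamma = 1)
classify_response(alpha = 0.5, gamma = 1)
perfect_strategy(payoff_spec("linear", alpha = 2), grid = c(0, 1, 2))
```

Two design choices here were genuinely open. At exactly $S = S_t$ both
boundary choices pay zero; we return $E = 0$ as the parsimonious tie-break.
And when an interior optimum exceeds a finite $E_{max}$ we clamp to
$E_{max}$, extending the concave-case boundary treatment to the convex case.

## Measurement noise and the Bayesian response

The readout is modeled as unbiased Gaussian error, $m \sim N(S, \sigma_m^2)$.
Because expectations preserve convexity, the structure of the optimum is
unchanged; for benefit *linear* in $S$, the expected payoff given $m$ depends
on the unknown $S$ only through the posterior mean $\mathbb{E}[S|m]$, so the
noisy-measurement optimum is the perfect-measurement optimum evaluated at
$\max(\mathbb{E}[S|m], 0)$. This composition fails for the Michaelis–Menten
benefit (nonlinear in $S$); that case is deliberately excluded from the
closed-form path and served by the quadrature oracle
(`posterior_functional_quadrature()`, computing $\mathbb{E}[S/(K_M+S)\,|\,m]$).

For a Gaussian environmental prior $N(\mu, \sigma_E^2)$,

$$\mathbb{E}[S|m] = \frac{m + \beta\mu}{1+\beta}, \qquad
  \beta = \frac{\sigma_m^2}{\sigma_E^2},$$

with posterior variance $\sigma_m^2/(1+\beta)$. The dimensionless $\beta$ —
the inverse signal-to-noise ratio — organizes the strategy regimes:
$\beta \ll 1$ makes the Bayesian strategy indistinguishable from *naive*
response ($E^*(m)$ as if $S = m$), $\beta \gg 1$ from *constitutive*
expression at $E^*(\mu)$, and intermediate $\beta$ yields a non-degenerate
Bayesian rule that mixes prior and measurement. The `beta` ordering of the
Results text and Models text of the source analyses differs verbally; we fix
$\beta = \sigma_m^2/\sigma_E^2$, the only reading consistent with the stated
limits.

For a Gaussian-mixture prior $\sum_i p_i N(\mu_i, \sigma_i^2)$ the posterior
mean is a responsibility-weighted sum of per-mode shrinkage estimates,

$$\mathbb{E}[S|m] = \sum_i w_i(m)\,\frac{m + \beta_i\mu_i}{1+\beta_i},
\qquad w_i(m) \propto p_i\, N(m;\, \mu_i,\, \sigma_i^2 + \sigma_m^2),$$

with $\beta_i = \sigma_m^2/\sigma_i^2$. Responsibilities are computed with a
log-sum-exp shift so that widely separated modes do not underflow. For the
equiprobable equal-variance bimodal environment (modes $\bar\mu \pm
\Delta\mu/2$) the weight difference collapses to
$\tanh\!\big[(m - \bar\mu)\Delta\mu / (2(\sigma_E^2 + \sigma_m^2))\big]$: the
optimal response is sigmoidal with steepness set by
$\Delta\mu/(\sigma_E^2+\sigma_m^2)$, which is how environmental statistics
set the effective cooperativity of an optimal biochemical switch.

Mode distinguishability is summarized by
$\xi = \sigma_m^2 / (\Delta\mu \sqrt{\sigma_E^2 + \sigma_m^2})$. The source
analysis defines $\xi$ only verbally (measurement uncertainty over the
product of mode separation and the typical distance of a measurement from the
mean); we read "uncertainty" as the variance and "typical distance" as the
total standard deviation, and expose the formula as a pluggable function in
`xi_ratio()` so alternative readings can be compared. $\xi \ll 1$ gives
*classification* (the posterior mean snaps to the nearer mode mean — note
this additionally requires $\sigma_m \gg \sigma_E$, so that within-mode
detail is unresolvable while the modes themselves are distinguishable),
$\xi \gg 1$ gives constitutive response at $\bar\mu$. Regime cut points in
`classify_measurement_regime()` default to 0.1 and 10; they are presentation
conveniences for order-of-magnitude language, and are configurable.

```{r}
prior <- gaussian_prior(mu = 1, sigma_E = 1)
meas <- measurement_model(sigma_m = 1) # beta = 1
posterior_mean_gaussian(3, prior, meas)
noisy_optimal_strategy(payoff_spec("linear", alpha = 2), prior, meas,
                       grid = seq(0, 4, by = 1))
```

Gaussian priors put mass on negative concentrations. We follow the analytic
treatment: posterior means are computed on the whole real line, and only the
*effective* nutrient estimate entering the static optimum is clamped at zero.
Monte-Carlo fitness likewise scores the linear benefit at the true (possibly
negative) $S$, matching the model under which the closed forms are optimal.
A truncated-prior variant is available through the quadrature oracle only.

## Dynamic environments and memory

Temporal structure is modeled as a stationary mean-reverting AR(1) chain:
$S_t \mid S_{t-1} \sim N(\lambda S_{t-1} + (1-\lambda)\mu,\ \sigma_d^2)$ with
$\sigma_d^2 = (1-\lambda^2)\sigma_E^2$, so the marginal is $N(\mu, \sigma_E^2)$
at every step by construction and the lag-$k$ autocorrelation is $\lambda^k$
(correlation time $\tau = -1/\ln\lambda$). We parametrize by
$(\mu, \sigma_E, \lambda)$ and derive $\sigma_d$, which enforces stationarity
rather than asserting it; $\lambda = 1$ is excluded (no stationary law). One
time step equals one measurement interval, and the cellular response is
assumed faster than environmental change (no response lag).

Because the state and the readouts are jointly Gaussian, the posterior mean
with memory is exactly linear:

$$\mathbb{E}[S_t \mid m_t, \ldots, m_{t-k}] = \mu + \sum_{j=0}^{k} w_j (m_{t-j} - \mu),
\qquad w = \Sigma_{mm}^{-1} c,$$

where $c_j = \lambda^j \sigma_E^2$ and $(\Sigma_{mm})_{ij} =
\lambda^{|i-j|}\sigma_E^2 + \delta_{ij}\sigma_m^2$. `memory_weights()` solves
this system for any $k$; `posterior_mean_memory1()` and
`posterior_mean_memory2()` are the $k = 1, 2$ cases the closed-form strategy
tables use. The estimator coincides exactly with a Kalman filter initialized
at the stationary prior and run over the retained readouts — the package
asserts this numerically against `kalman_filter()` across random parameter
draws rather than by transcription, and additionally against a least-squares
regression of simulated $S_t$ on $(m_t, m_{t-1})$, which is a valid oracle
precisely because the conditional mean is linear. The weight on the past
readout vanishes at $\lambda = 0$ and at $\sigma_m = 0$ and is strictly
positive otherwise; retaining more history never increases the filter's
mean-squared error. Memories longer than two steps are supported only through
the Kalman recursion (the explicit weight expressions grow cumbersome without
adding structure).

## Simulator

`simulate_trajectory()` draws $S_0$ from the stationary marginal and iterates
the conditional law; `add_measurements()` adds i.i.d. Gaussian readout noise.
The environment and measurement streams use independent sub-seeds derived
from one user seed (a MINSTD step), so measurement noise can be re-drawn or
re-scaled while holding the environmental path fixed — this is what makes the
value-of-memory comparisons paired. The generator emulates exactly the
distributional assumptions of the analysis (Gaussian or mixture marginals,
AR(1) dynamics, unbiased Gaussian error); it does *not* emulate features of
real nutrient time series such as skewness, heavy tails, multiplicative
noise, or measurement bias, so passing tests certify the mathematics, not
robustness to model misspecification.

## Fitness comparisons

`compare_strategies()` scores naive, constitutive, Bayesian, and (for Markov
environments) memory-1/2 strategies on a common set of simulated draws, so
differences carry paired standard errors. `value_of_memory()` is the mean
payoff of the memory-1 Bayesian strategy minus the memoryless Bayesian
strategy on the same trajectory; the source analysis never fixes a
quantitative functional for the "value of memory", and this payoff difference
is the natural reading. `regime_map()` sweeps $\beta$ (and $\lambda$) and
reports the winner per cell. The claims these reproduce are ordinal — winner
identity at the extremes, an interior peak of the memory value — not numeric
targets.

```{r, fig.width = 5, fig.height = 3}
spec <- payoff_spec("linear", alpha = 2)
env <- markov_env(mu = 1, sigma_E = 1, lam = 0.9)
sweep <- value_of_memory_sweep(spec, env, beta = 10^(-2:2), n = 2e4, seed = 1)
sweep
plot_memory_value(sweep)
```

## Numerical choices

* **Quadrature oracle.** Posterior expectations integrate over a window
  covering $\pm 8$ combined standard deviations around every prior center and
  the readout. The window is split into 128 uniform panels plus panels at the
  likelihood's own scale around $m$, each integrated adaptively, so neither a
  narrow prior mode nor a narrow likelihood can be missed; the integrand is
  rescaled by its probe-grid peak so readouts deep in the prior tail retain
  relative accuracy. Results are invariant (to $10^{-8}$) under doubling the
  window.
* **Grid-search oracle.** Enzyme grids default to $10^{-4}$ steps; ties
  resolve to the smallest enzyme level.
* **Monte-Carlo scale.** Unit tests use $10^4$–$10^6$ draws; the full-scale
  property checks use $10^5$ (simulator statistics), $10^6$ (fitness
  ordering per sweep cell), and $10^7$ (regression oracle for the memory
  estimator), with all statistical assertions at three standard errors of
  the quantity under test.
* **Degenerate inputs.** $\sigma_m = 0$ short-circuits to perfect
  measurement everywhere; $\Delta\mu = 0$ makes $\xi = +\infty$ by
  convention; readouts outside a strategy table's grid clamp to the edge
  levels; strategies interpolate linearly (bilinearly in 2-D) between nodes.

## Limitations

Single enzyme, single nutrient; costs depend only on the current enzyme
level (no time-integrated or regulatory-machinery costs); fitness is the
payoff mean only; measurement error is unbiased and Gaussian; the
Michaelis–Menten benefit under noise has no closed-form strategy here (use
the quadrature path); and mixed (stochastic) strategies are out of scope —
with mean-only fitness a deterministic optimum always exists.
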