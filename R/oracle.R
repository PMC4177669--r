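#' Posterior mean by adaptive quadrature (brute-force reference)
#'
#' Computes \eqn{E[S|m] = \int S\,p(S)\,N(m; S, \sigma_m^2)\,dS \,/\,
#' \int p(S)\,N(m; S, \sigma_m^2)\,dS} by adaptive quadrature against an
#' arbitrary prior density. Used as the independent oracle for every
#' closed-form posterior mean; clarity over speed.
#'
#' @param m A single readout value.
#' @param density Vectorized prior density `function(S)`.
#' @param meas A [measurement_model()] with `sigma_m > 0`.
#' @param bounds Integration window `c(lower, upper)`; should cover at least
#'   +/- 8 combined standard deviations around the relevant centers.
#' @return The posterior mean (scalar).
#' @export
posterior_mean_quadrature <- function(m, density, meas, bounds) {
  posterior_functional_quadrature(m, function(S) S, density, meas, bounds)
}

#' Posterior expectation of an arbitrary function of the nutrient level
#'
#' \eqn{E[f(S)|m]} by adaptive quadrature; `f = identity` recovers
#' [posterior_mean_quadrature()]. Used for expectations with no closed form,
#' e.g. the saturating Michaelis-Menten factor \eqn{E[S/(K_M+S)|m]} and
#' truncated-prior variants.
#'
#' @inheritParams posterior_mean_quadrature
#' @param f Vectorized function of S.
#' @return The posterior expectation (scalar).
#' @export
posterior_functional_quadrature <- function(m, f, density, meas, bounds) {
  stopifnot(length(m) == 1L, is.finite(m), is.function(f),
            is.function(density), inherits(meas, "measurement_model"),
            length(bounds) == 2L, bounds[1] < bounds[2])
  lik <- function(S) density(S) * stats::dnorm(m, S, meas$sigma_m)
  # Integrate over fixed panels: uniform subdivision of the window (so narrow
  # prior modes anywhere in it cannot be skipped by the adaptive rule's
  # initial sampling) plus panels at the likelihood's own scale around m (so
  # a likelihood spike much narrower than the window is resolved too).
  lik_edges <- m + meas$sigma_m * c(-12, -8, -4, -2, -1, 0, 1, 2, 4, 8, 12)
  edges <- sort(unique(c(
    seq(bounds[1], bounds[2], length.out = 129L),
    lik_edges[lik_edges > bounds[1] & lik_edges < bounds[2]]
  )))
  # Rescale by the peak integrand value seen on a probe grid so tail readouts
  # (tiny absolute integrals) keep full relative accuracy.
  probes <- c(seq(bounds[1], bounds[2], length.out = 512L),
              lik_edges[lik_edges >= bounds[1] & lik_edges <= bounds[2]])
  scale <- max(lik(probes))
  if (!is.finite(scale) || scale <= 0) {
    stop("Readout has vanishing support on the integration window.",
         call. = FALSE)
  }
  panel_int <- function(g) {
    total <- 0
    for (j in seq_len(length(edges) - 1L)) {
      total <- total + stats::integrate(g, edges[j], edges[j + 1L],
                                        abs.tol = 1e-12, rel.tol = 1e-10,
                                        subdivisions = 200L)$value
    }
    total
  }
  denom <- panel_int(function(S) lik(S) / scale)
  if (denom <= 1e-290) {
    stop("Readout has vanishing support on the integration window.",
         call. = FALSE)
  }
  num <- panel_int(function(S) f(S) * lik(S) / scale)
  num / denom
}

#' Default integration window for a prior and measurement model
#'
#' Covers +/- `k` combined standard deviations around all relevant centers
#' (prior mode means and the readout).
#'
#' @param prior A [gaussian_prior()] or [mixture_prior()].
#' @param meas A [measurement_model()].
#' @param m Readout value(s) to cover.
#' @param k Number of combined standard deviations (default 8).
#' @return Length-2 numeric `c(lower, upper)`.
#' @export
quadrature_bounds <- function(prior, meas, m, k = 8) {
  centers <- c(if (inherits(prior, "gaussian_prior")) prior$mu else prior$means, m)
  sd_max <- sqrt(prior_sd_total(prior)^2 + meas$sigma_m^2)
  c(min(centers) - k * sd_max, max(centers) + k * sd_max)
}

#' Payoff-maximizing enzyme level by grid search (brute-force reference)
#'
#' Argmax of the payoff over an explicit enzyme grid; ties resolve to the
#' smallest enzyme level. The oracle for the closed-form static optima.
#'
#' @param spec A [payoff_spec()].
#' @param S_eff Effective (known or expected) nutrient level.
#' @param E_grid Enzyme grid within `[0, E_max]`.
#' @return The grid point maximizing the payoff.
#' @export
optimal_enzyme_grid <- function(spec, S_eff, E_grid) {
  stopifnot(inherits(spec, "payoff_spec"), length(E_grid) >= 1L)
  if (any(E_grid < 0) || any(E_grid > spec$E_max)) {
    stop("`E_grid` must lie within [0, E_max].", call. = FALSE)
  }
  p <- payoff(spec, E_grid, max(S_eff, 0))
  E_grid[which.max(p)]
}

#' Kalman filter for the AR(1) nutrient environment (reference recursion)
#'
#' Standard linear-Gaussian filtering recursion, initialized at the stationary
#' prior \eqn{N(\mu, \sigma_E^2)}, run over a sequence of readouts. After
#' observing \eqn{(m_{t-k}, ..., m_t)} the filtered mean equals
#' \eqn{E[S_t | m_{t-k}, \ldots, m_t]}; it is the oracle for the closed-form
#' memory posterior means.
#'
#' @param m Numeric vector of readouts in time order.
#' @param env A [markov_env()].
#' @param meas A [measurement_model()].
#' @return A tibble with columns `step`, `filtered_mean`, `filtered_var`.
#' @export
kalman_filter <- function(m, env, meas) {
  stopifnot(inherits(env, "markov_env"), inherits(meas, "measurement_model"),
            length(m) >= 1L)
  n <- length(m)
  mean_pred <- env$mu
  var_pred <- env$sigma_E^2
  fm <- numeric(n)
  fv <- numeric(n)
  for (t in seq_len(n)) {
    if (meas$sigma_m == 0) {
      fm[t] <- m[t]
      fv[t] <- 0
    } else {
      K <- var_pred / (var_pred + meas$sigma_m^2)
      fm[t] <- mean_pred + K * (m[t] - mean_pred)
      fv[t] <- (1 - K) * var_pred
    }
    mean_pred <- env$lam * fm[t] + (1 - env$lam) * env$mu
    var_pred <- env$lam^2 * fv[t] + env$sigma_d^2
  }
  tibble::tibble(step = seq_len(n) - 1L, filtered_mean = fm, filtered_var = fv)
}

#' Monte-Carlo expected fitness of a tabulated strategy
#'
#' Simulates (S, m) pairs under the stated environment and measurement model,
#' applies the strategy by (bi)linear interpolation (clamping outside the
#' grid), and returns the mean payoff with its Monte-Carlo standard error.
#' Memory-one (2-D) strategies require a Markov environment; the first step of
#' each trajectory is dropped since it has no previous readout.
#'
#' @param strategy A [strategy_table].
#' @param env_model A [gaussian_prior()], [mixture_prior()], or [markov_env()].
#' @param meas A [measurement_model()].
#' @param spec A [payoff_spec()] used to score the payoff against the true S.
#' @param n Number of Monte-Carlo pairs (>= 100).
#' @param seed Integer seed.
#' @return A tibble with columns `mean_payoff`, `se`, `n`.
#' @export
expected_fitness_mc <- function(strategy, env_model, meas, spec, n, seed) {
  stopifnot(inherits(strategy, "strategy_table"),
            inherits(meas, "measurement_model"),
            inherits(spec, "payoff_spec"))
  if (n < 100) stop("Need n >= 100 for a meaningful standard error.", call. = FALSE)
  is_memory <- all(c("m_t", "m_prev") %in% names(strategy))
  if (inherits(env_model, "markov_env")) {
    steps <- if (is_memory) n + 1L else n
    traj <- simulate_readouts(env_model, meas, steps, seed)
    if (is_memory) {
      S <- traj$S[-1]
      E <- apply_strategy(strategy, cbind(traj$m[-1], traj$m[-nrow(traj)]))
    } else {
      S <- traj$S
      E <- apply_strategy(strategy, traj$m)
    }
  } else {
    if (is_memory) {
      stop("Memory strategies require a Markov environment.", call. = FALSE)
    }
    S <- sample_static(env_model, n, seed)
    m <- add_measurements(S, meas, seed)
    E <- apply_strategy(strategy, m)
  }
  p <- score_payoff(spec, E, S)
  tibble::tibble(mean_payoff = mean(p),
                 se = stats::sd(p) / sqrt(length(p)),
                 n = length(p))
}
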