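# Deterministic sub-seed derivation (MINSTD step) so environment and
# measurement noise use independent, individually reproducible streams.
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  x <- (abs(seed) %% 2147483646) + 1
  for (i in seq_len(stream + 1L)) x <- (x * 48271) %% 2147483647
  as.integer(x)
}

#' Sample nutrient levels from a static environmental prior
#'
#' Independent draws from a Gaussian or Gaussian-mixture environment.
#' Bit-reproducible given `seed`.
#'
#' @param prior A [gaussian_prior()] or [mixture_prior()].
#' @param n Number of draws (>= 1).
#' @param seed Integer seed.
#' @return Numeric vector of nutrient levels.
#' @export
sample_static <- function(prior, n, seed) {
  stopifnot(n >= 1)
  set.seed(derive_seed(seed, 0L))
  if (inherits(prior, "gaussian_prior")) {
    stats::rnorm(n, prior$mu, prior$sigma_E)
  } else if (inherits(prior, "mixture_prior")) {
    comp <- sample.int(length(prior$weights), n, replace = TRUE,
                       prob = prior$weights)
    stats::rnorm(n, prior$means[comp], prior$sds[comp])
  } else {
    stop("Unsupported prior class.", call. = FALSE)
  }
}

#' Simulate a mean-reverting nutrient trajectory
#'
#' \eqn{S_0} is drawn from the stationary marginal \eqn{N(\mu, \sigma_E^2)};
#' subsequent steps from \eqn{N(\lambda S_{t-1} + (1-\lambda)\mu, \sigma_d^2)}.
#'
#' @param env A [markov_env()].
#' @param n_steps Number of time steps (>= 1).
#' @param seed Integer seed.
#' @return A tibble with columns `step` (0-based) and `S`.
#' @export
simulate_trajectory <- function(env, n_steps, seed) {
  stopifnot(inherits(env, "markov_env"), n_steps >= 1)
  set.seed(derive_seed(seed, 0L))
  innov <- stats::rnorm(n_steps, 0, 1)
  S <- numeric(n_steps)
  S[1] <- env$mu + env$sigma_E * innov[1]
  if (n_steps > 1) {
    for (t in 2:n_steps) {
      S[t] <- env$lam * S[t - 1] + (1 - env$lam) * env$mu +
        env$sigma_d * innov[t]
    }
  }
  tibble::tibble(step = seq_len(n_steps) - 1L, S = S)
}

#' Add noisy readouts to true nutrient levels
#'
#' \eqn{m_i = S_i + \epsilon_i}, \eqn{\epsilon_i \sim N(0, \sigma_m^2)} i.i.d.
#' The measurement stream is seeded independently of the environment stream,
#' so measurement noise can be varied while holding a trajectory fixed.
#'
#' @param S Numeric vector of true nutrient levels, or a tibble with an `S`
#'   column (e.g. from [simulate_trajectory()]).
#' @param meas A [measurement_model()].
#' @param seed Integer seed.
#' @return Readout vector, or the input tibble with an added `m` column.
#' @export
add_measurements <- function(S, meas, seed) {
  stopifnot(inherits(meas, "measurement_model"))
  is_tbl <- is.data.frame(S)
  s_vec <- if (is_tbl) S$S else S
  if (meas$sigma_m == 0) {
    m <- s_vec
  } else {
    set.seed(derive_seed(seed, 1L))
    m <- s_vec + stats::rnorm(length(s_vec), 0, meas$sigma_m)
  }
  if (is_tbl) {
    S$m <- m
    S
  } else {
    m
  }
}

#' Simulate a full trajectory of true levels and noisy readouts
#'
#' Convenience composition of [simulate_trajectory()] and
#' [add_measurements()], using independent environment and measurement
#' sub-streams derived from one seed.
#'
#' @inheritParams simulate_trajectory
#' @param meas A [measurement_model()].
#' @return A tibble with columns `step`, `S`, `m`.
#' @export
simulate_readouts <- function(env, meas, n_steps, seed) {
  add_measurements(simulate_trajectory(env, n_steps, seed), meas, seed)
}
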