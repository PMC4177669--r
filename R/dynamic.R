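#' Posterior-mean weights for AR(1) environments with measurement memory
#'
#' Under the stationary mean-reverting environment and unbiased Gaussian
#' readouts, (S_t, m_t, m_{t-1}, ..., m_{t-k}) are jointly Gaussian, so
#' \deqn{E[S_t | m_t, \ldots, m_{t-k}] = \mu + \sum_{j=0}^{k} w_j (m_{t-j} - \mu)}
#' with weights obtained by Gaussian conditioning:
#' \eqn{w = \Sigma_{mm}^{-1} c}, where \eqn{c_j = \lambda^j \sigma_E^2} is the
#' covariance of S_t with m_{t-j} and \eqn{\Sigma_{mm}} has entries
#' \eqn{\lambda^{|i-j|}\sigma_E^2 + \delta_{ij}\sigma_m^2}.
#'
#' @param env A [markov_env()].
#' @param meas A [measurement_model()].
#' @param k Number of past measurements retained (0 = memoryless).
#' @return Numeric weight vector of length `k + 1` (current readout first).
#' @export
memory_weights <- function(env, meas, k = 1) {
  stopifnot(inherits(env, "markov_env"), inherits(meas, "measurement_model"),
            k >= 0)
  if (meas$sigma_m == 0) return(c(1, rep(0, k)))
  lags <- 0:k
  c_vec <- env$lam^lags * env$sigma_E^2
  Sigma <- env$sigma_E^2 * env$lam^abs(outer(lags, lags, "-")) +
    diag(meas$sigma_m^2, k + 1)
  as.numeric(solve(Sigma, c_vec))
}

#' Expected nutrient level given current and previous readouts
#'
#' The two-observation posterior mean \eqn{E[S_t | m_t, m_{t-1}]} for the
#' stationary AR(1) environment with Gaussian readout noise. Because the
#' model is linear-Gaussian this coincides exactly with a Kalman filter
#' initialized at the stationary prior and updated with the two observations.
#'
#' @param m_t Current readout(s).
#' @param m_prev Previous readout(s); recycled against `m_t`.
#' @param env A [markov_env()].
#' @param meas A [measurement_model()].
#' @return Posterior mean(s).
#' @examples
#' env <- markov_env(mu = 0, sigma_E = 1, lam = 0.9)
#' posterior_mean_memory1(1, 2, env, measurement_model(1))
#' @export
posterior_mean_memory1 <- function(m_t, m_prev, env, meas) {
  w <- memory_weights(env, meas, k = 1)
  env$mu + w[1] * (m_t - env$mu) + w[2] * (m_prev - env$mu)
}

#' Expected nutrient level given the three most recent readouts
#'
#' \eqn{E[S_t | m_t, m_{t-1}, m_{t-2}]} by 4-variate Gaussian conditioning.
#' Reduces to [posterior_mean_memory1()] when `lam = 0` (the chain forgets
#' instantly) and to `m_t` when `sigma_m = 0`.
#'
#' @inheritParams posterior_mean_memory1
#' @param m_prev2 Readout two steps back.
#' @return Posterior mean(s).
#' @export
posterior_mean_memory2 <- function(m_t, m_prev, m_prev2, env, meas) {
  w <- memory_weights(env, meas, k = 2)
  env$mu + w[1] * (m_t - env$mu) + w[2] * (m_prev - env$mu) +
    w[3] * (m_prev2 - env$mu)
}

#' Tabulate the optimal memory-one strategy for a dynamic environment
#'
#' For benefit linear in the nutrient level, the optimal enzyme level given
#' (m_t, m_prev) is the static optimum evaluated at the clamped posterior mean
#' \eqn{\max(E[S_t|m_t, m_{t-1}], 0)}. Returned on a 2-D readout grid.
#'
#' @param spec A [payoff_spec()] with linear benefit.
#' @param env A [markov_env()].
#' @param meas A [measurement_model()].
#' @param grid_m Strictly increasing grid for the current readout.
#' @param grid_prev Grid for the previous readout (defaults to `grid_m`).
#' @return A [strategy_table] with columns `m_t`, `m_prev`, `enzyme_level`.
#' @export
dynamic_optimal_strategy <- function(spec, env, meas, grid_m,
                                     grid_prev = grid_m) {
  stopifnot(inherits(spec, "payoff_spec"))
  if (spec$benefit_mode == "michaelis_menten" && meas$sigma_m > 0) {
    stop("Michaelis-Menten benefit under noise is not a posterior-mean ",
         "composition; see posterior_functional_quadrature().", call. = FALSE)
  }
  check_grid(grid_m)
  check_grid(grid_prev)
  tab <- tidyr::expand_grid(m_prev = as.numeric(grid_prev),
                            m_t = as.numeric(grid_m))
  S_eff <- pmax(posterior_mean_memory1(tab$m_t, tab$m_prev, env, meas), 0)
  tab$enzyme_level <- optimal_enzyme(spec, S_eff)
  new_strategy_table(
    tab[, c("m_t", "m_prev", "enzyme_level")],
    meta = list(kind = "bayes_memory1", spec = spec, env = env, meas = meas)
  )
}
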