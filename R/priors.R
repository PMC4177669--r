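#' Gaussian prior over environmental nutrient concentration
#'
#' A static environment in which the nutrient level at any instant is drawn
#' independently from \eqn{N(\mu, \sigma_E^2)}.
#'
#' @param mu Mean nutrient level.
#' @param sigma_E Positive environmental standard deviation.
#' @return Object of class `gaussian_prior`.
#' @export
gaussian_prior <- function(mu = 0, sigma_E = 1) {
  stopifnot(is.numeric(mu), length(mu) == 1L, is.finite(mu),
            is.numeric(sigma_E), length(sigma_E) == 1L, sigma_E > 0)
  structure(list(mu = mu, sigma_E = sigma_E),
            class = c("gaussian_prior", "nutrient_prior"))
}

#' Gaussian-mixture prior over environmental nutrient concentration
#'
#' An environment that fluctuates between several modes, each Gaussian.
#' The canonical bimodal case (scarcity versus abundance) is an equiprobable
#' mixture of two equal-variance Gaussians separated by `delta_mu`; use
#' [bimodal_prior()] for that parametrization.
#'
#' @param weights Mode probabilities; must sum to 1 (tolerance 1e-12).
#' @param means Mode means (same length as `weights`).
#' @param sds Positive within-mode standard deviations (same length).
#' @return Object of class `mixture_prior` with derived fields `mu_bar` (the
#'   overall mean) and, for two-component mixtures, `delta_mu`.
#' @export
mixture_prior <- function(weights, means, sds) {
  stopifnot(length(weights) >= 1L,
            length(weights) == length(means),
            length(weights) == length(sds),
            all(weights >= 0), all(sds > 0),
            all(is.finite(c(weights, means, sds))))
  if (abs(sum(weights) - 1) > 1e-12) {
    stop("Mixture weights must sum to 1 (within 1e-12).", call. = FALSE)
  }
  out <- list(weights = as.numeric(weights), means = as.numeric(means),
              sds = as.numeric(sds), mu_bar = sum(weights * means))
  if (length(weights) == 2L) out$delta_mu <- abs(means[2] - means[1])
  structure(out, class = c("mixture_prior", "nutrient_prior"))
}

#' Equiprobable bimodal environment
#'
#' Two equal-variance Gaussian modes with means \eqn{\bar\mu \pm \Delta\mu/2}.
#'
#' @param mu_bar Overall environmental mean.
#' @param delta_mu Non-negative separation between the two mode means.
#' @param sigma_E Positive within-mode standard deviation.
#' @return A two-component [mixture_prior()].
#' @export
bimodal_prior <- function(mu_bar = 0, delta_mu = 2, sigma_E = 0.2) {
  stopifnot(delta_mu >= 0)
  mixture_prior(weights = c(0.5, 0.5),
                means = mu_bar + c(-0.5, 0.5) * delta_mu,
                sds = c(sigma_E, sigma_E))
}

#' Unbiased Gaussian measurement model
#'
#' The cellular readout m of a true nutrient level S is
#' \eqn{m = S + \epsilon}, \eqn{\epsilon \sim N(0, \sigma_m^2)}.
#' `sigma_m = 0` is perfect measurement.
#'
#' @param sigma_m Non-negative readout standard deviation.
#' @return Object of class `measurement_model`.
#' @export
measurement_model <- function(sigma_m) {
  stopifnot(is.numeric(sigma_m), length(sigma_m) == 1L,
            is.finite(sigma_m), sigma_m >= 0)
  structure(list(sigma_m = sigma_m), class = "measurement_model")
}

#' Stationary mean-reverting Markov (AR(1)) environment
#'
#' Discrete-time environment with conditional law
#' \eqn{S_t | S_{t-1} \sim N(\lambda S_{t-1} + (1-\lambda)\mu, \sigma_d^2)}
#' and stationary marginal \eqn{N(\mu, \sigma_E^2)}. The innovation variance
#' \eqn{\sigma_d^2 = (1-\lambda^2)\sigma_E^2} is derived so stationarity holds
#' by construction; lag-k autocorrelation is \eqn{\lambda^k}.
#'
#' @param mu Stationary mean nutrient level.
#' @param sigma_E Positive stationary standard deviation.
#' @param lam Persistence \eqn{\lambda \in [0, 1)}; the lag-1 autocorrelation.
#' @return Object of class `markov_env` with derived `sigma_d`.
#' @export
markov_env <- function(mu = 0, sigma_E = 1, lam = 0.9) {
  stopifnot(is.numeric(mu), length(mu) == 1L, is.finite(mu),
            is.numeric(sigma_E), length(sigma_E) == 1L, sigma_E > 0,
            is.numeric(lam), length(lam) == 1L)
  if (lam < 0 || lam >= 1) {
    stop("Persistence `lam` must lie in [0, 1).", call. = FALSE)
  }
  structure(
    list(mu = mu, sigma_E = sigma_E, lam = lam,
         sigma_d = sigma_E * sqrt(1 - lam^2)),
    class = "markov_env"
  )
}

#' Correlation time of a mean-reverting environment
#'
#' Autocorrelation decays geometrically, \eqn{\rho(k) = \lambda^k = e^{-k/\tau}},
#' so the correlation time in measurement steps is \eqn{\tau = -1/\ln\lambda}.
#' By convention `lam = 0` (memoryless) returns 0.
#'
#' @param lam Persistence in `[0, 1)`.
#' @return Correlation time in discrete steps; 0 at `lam = 0`.
#' @export
correlation_time <- function(lam) {
  stopifnot(is.numeric(lam), all(lam >= 0), all(lam < 1))
  ifelse(lam == 0, 0, -1 / log(lam))
}

#' Prior density function
#'
#' Returns the probability density of a nutrient prior as a vectorized
#' function of S, for use with the quadrature oracles.
#'
#' @param prior A [gaussian_prior()] or [mixture_prior()].
#' @return Function `function(S)` giving the prior density.
#' @export
prior_density <- function(prior) {
  UseMethod("prior_density")
}

#' @export
prior_density.gaussian_prior <- function(prior) {
  function(S) stats::dnorm(S, prior$mu, prior$sigma_E)
}

#' @export
prior_density.mixture_prior <- function(prior) {
  function(S) {
    out <- 0
    for (i in seq_along(prior$weights)) {
      out <- out + prior$weights[i] * stats::dnorm(S, prior$means[i], prior$sds[i])
    }
    out
  }
}

prior_mean <- function(prior) {
  if (inherits(prior, "gaussian_prior")) prior$mu else prior$mu_bar
}

prior_sd_total <- function(prior) {
  if (inherits(prior, "gaussian_prior")) return(prior$sigma_E)
  m2 <- sum(prior$weights * (prior$sds^2 + prior$means^2))
  sqrt(m2 - prior_mean(prior)^2)
}
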