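#' Inverse signal-to-noise ratio beta
#'
#' \eqn{\beta = \sigma_m^2 / \sigma_E^2}, the ratio of measurement-error
#' variance to environmental variance. `beta << 1` means a single readout
#' pins down the nutrient level (naive response optimal); `beta >> 1` means
#' the readout carries almost no information beyond the prior (constitutive
#' expression optimal).
#'
#' @param prior A [gaussian_prior()] (or any prior with a total standard
#'   deviation; for mixtures the within-mode interpretation uses per-mode
#'   ratios internally).
#' @param meas A [measurement_model()].
#' @return Non-negative dimensionless ratio.
#' @export
beta_ratio <- function(prior, meas) {
  stopifnot(inherits(meas, "measurement_model"))
  sigma_E <- if (inherits(prior, "gaussian_prior")) prior$sigma_E
             else prior_sd_total(prior)
  meas$sigma_m^2 / sigma_E^2
}

#' Posterior mean nutrient level: Gaussian prior
#'
#' With prior \eqn{S \sim N(\mu, \sigma_E^2)} and readout
#' \eqn{m | S \sim N(S, \sigma_m^2)}, the posterior of S given m is Gaussian
#' with mean \eqn{(m + \beta\mu)/(1+\beta)} and variance
#' \eqn{\sigma_m^2/(1+\beta)}, where \eqn{\beta = \sigma_m^2/\sigma_E^2}.
#'
#' @param m Readout value(s); vectorized.
#' @param prior A [gaussian_prior()].
#' @param meas A [measurement_model()].
#' @param with_variance If `TRUE`, return a tibble with columns `m`,
#'   `posterior_mean`, `posterior_var`; otherwise the posterior mean vector.
#' @return Posterior mean(s), or a tibble when `with_variance = TRUE`.
#' @examples
#' posterior_mean_gaussian(2, gaussian_prior(0, 1), measurement_model(1))
#' @export
posterior_mean_gaussian <- function(m, prior, meas, with_variance = FALSE) {
  stopifnot(inherits(prior, "gaussian_prior"),
            inherits(meas, "measurement_model"))
  beta <- meas$sigma_m^2 / prior$sigma_E^2
  pm <- (m + beta * prior$mu) / (1 + beta)
  if (!with_variance) return(pm)
  tibble::tibble(m = m, posterior_mean = pm,
                 posterior_var = meas$sigma_m^2 / (1 + beta))
}

#' Posterior mean nutrient level: uniform (uninformative) prior
#'
#' A flat prior carries no information, so the posterior mean is the readout
#' itself and the optimal response is unchanged from perfect detection.
#'
#' @param m Readout value(s).
#' @return `m`, unchanged (any clamping to physical concentrations happens
#'   downstream in strategy construction).
#' @export
posterior_mean_uniform <- function(m) {
  stopifnot(is.numeric(m))
  m
}

#' Posterior mean nutrient level: Gaussian-mixture prior
#'
#' For a mixture prior \eqn{\sum_i p_i N(\mu_i, \sigma_i^2)} the posterior
#' mean is a responsibility-weighted sum of per-mode Gaussian posterior means:
#' \deqn{E[S|m] = \sum_i w_i(m)\,\frac{m + \beta_i \mu_i}{1 + \beta_i},\qquad
#'   w_i(m) \propto p_i\,N(m; \mu_i, \sigma_i^2 + \sigma_m^2),}
#' with \eqn{\beta_i = \sigma_m^2/\sigma_i^2}. For the equiprobable
#' equal-variance bimodal case this reduces to a tanh-shaped switch between
#' the two per-mode estimates: the mode-weight difference is
#' \eqn{\tanh[(m-\bar\mu)\,\Delta\mu / (2(\sigma_E^2+\sigma_m^2))]}, so the
#' steepness of the optimal sigmoidal response is set by
#' \eqn{\Delta\mu/(\sigma_E^2+\sigma_m^2)}.
#'
#' Responsibilities are computed with log-weights and a log-sum-exp shift, so
#' widely separated modes do not underflow.
#'
#' @param m Readout value(s); vectorized.
#' @param prior A [mixture_prior()].
#' @param meas A [measurement_model()].
#' @return Posterior mean(s).
#' @export
posterior_mean_mixture <- function(m, prior, meas) {
  stopifnot(inherits(prior, "mixture_prior"),
            inherits(meas, "measurement_model"))
  if (length(prior$weights) == 0L) {
    stop("Mixture prior has no components.", call. = FALSE)
  }
  sm2 <- meas$sigma_m^2
  K <- length(prior$weights)
  logw <- matrix(NA_real_, length(m), K)
  permode <- matrix(NA_real_, length(m), K)
  for (i in seq_len(K)) {
    tot_sd <- sqrt(prior$sds[i]^2 + sm2)
    logw[, i] <- log(prior$weights[i]) + stats::dnorm(m, prior$means[i], tot_sd, log = TRUE)
    beta_i <- sm2 / prior$sds[i]^2
    permode[, i] <- (m + beta_i * prior$means[i]) / (1 + beta_i)
  }
  shift <- apply(logw, 1, max)
  w <- exp(logw - shift)
  w <- w / rowSums(w)
  rowSums(w * permode)
}

#' Posterior mean dispatcher
#'
#' Routes to the closed form matching the prior family.
#'
#' @inheritParams posterior_mean_mixture
#' @param prior A [gaussian_prior()] or [mixture_prior()], or `NULL` for an
#'   uninformative prior.
#' @return Posterior mean(s).
#' @export
posterior_mean <- function(m, prior, meas) {
  if (is.null(prior)) return(posterior_mean_uniform(m))
  if (inherits(prior, "gaussian_prior")) posterior_mean_gaussian(m, prior, meas)
  else if (inherits(prior, "mixture_prior")) posterior_mean_mixture(m, prior, meas)
  else stop("Unsupported prior class.", call. = FALSE)
}

#' Mode-distinguishability ratio xi for bimodal environments
#'
#' \eqn{\xi = \sigma_m^2 / (\Delta\mu\,\sqrt{\sigma_E^2 + \sigma_m^2})}: the
#' measurement uncertainty (variance) relative to the product of the mode
#' separation and the typical distance of a readout from a mode mean (total
#' standard deviation). Small xi: the two modes are cleanly distinguishable
#' and the optimal strategy classifies the environment; large xi: the modes
#' are indistinguishable and constitutive expression at the overall mean is
#' optimal. The formula is swappable via `fun` so alternative readings of the
#' verbal definition can be compared.
#'
#' @param prior A two-component [mixture_prior()] with equal sds.
#' @param meas A [measurement_model()].
#' @param fun Optional replacement `function(delta_mu, sigma_E, sigma_m)`.
#' @return Non-negative xi; `Inf` when `delta_mu = 0` with noise present.
#' @export
xi_ratio <- function(prior, meas, fun = NULL) {
  stopifnot(inherits(prior, "mixture_prior"),
            inherits(meas, "measurement_model"))
  if (length(prior$weights) != 2L) {
    stop("xi is defined for bimodal priors.", call. = FALSE)
  }
  delta_mu <- prior$delta_mu
  sigma_E <- prior$sds[1]
  sigma_m <- meas$sigma_m
  if (!is.null(fun)) return(fun(delta_mu, sigma_E, sigma_m))
  if (sigma_m == 0) return(0)
  if (delta_mu == 0) return(Inf)
  sigma_m^2 / (delta_mu * sqrt(sigma_E^2 + sigma_m^2))
}

#' Classify the measurement-noise regime
#'
#' For unimodal (Gaussian) environments, beta partitions strategies into
#' naive (low noise), non-degenerate Bayesian (intermediate), and constitutive
#' (high noise). For bimodal environments the analogous partition on xi is
#' classification / ambiguous / constitutive. Cut points default to an order
#' of magnitude either side of 1.
#'
#' @param value The dimensionless ratio (beta or xi).
#' @param family `"unimodal"` (beta) or `"bimodal"` (xi).
#' @param low,high Cut points (defaults 0.1 and 10).
#' @return Regime label (character).
#' @examples
#' classify_measurement_regime(1e-3, "unimodal")
#' classify_measurement_regime(1, "bimodal")
#' @export
classify_measurement_regime <- function(value, family = c("unimodal", "bimodal"),
                                        low = 0.1, high = 10) {
  family <- match.arg(family)
  stopifnot(is.numeric(value), all(value >= 0), low < high)
  labels <- if (family == "unimodal") {
    c("naive", "bayesian", "constitutive")
  } else {
    c("classification", "ambiguous", "constitutive")
  }
  out <- ifelse(value < low, labels[1], ifelse(value > high, labels[3], labels[2]))
  out
}

#' Tabulate the optimal strategy under noisy measurement
#'
#' Because the benefit is linear in the nutrient level, the expected payoff
#' given a readout m depends on the unknown S only through its posterior mean,
#' so the noisy-measurement optimum is the perfect-measurement optimum
#' evaluated at \eqn{\max(E[S|m], 0)}: graded composition in the convex-cost
#' regime, thresholding of the posterior mean against the nutrient threshold
#' in the concave regime. Michaelis-Menten benefit is nonlinear in S, so its
#' noisy optimum has no such composition; use
#' [posterior_functional_quadrature()] for that case.
#'
#' @param spec A [payoff_spec()] with `benefit_mode = "linear"` (or
#'   `"power_law"` for the graded composition in S-linear benefit).
#' @param prior A [gaussian_prior()] or [mixture_prior()], or `NULL`
#'   (uninformative).
#' @param meas A [measurement_model()].
#' @param grid Strictly increasing readout grid.
#' @return A [strategy_table] with columns `readout`, `enzyme_level`.
#' @examples
#' spec <- payoff_spec("linear", alpha = 2)
#' noisy_optimal_strategy(spec, gaussian_prior(1, 1), measurement_model(1),
#'                        grid = seq(-2, 4, by = 0.5))
#' @export
noisy_optimal_strategy <- function(spec, prior, meas, grid) {
  stopifnot(inherits(spec, "payoff_spec"), inherits(meas, "measurement_model"))
  if (spec$benefit_mode == "michaelis_menten" && meas$sigma_m > 0) {
    stop("Michaelis-Menten benefit is nonlinear in the nutrient level, so the ",
         "noisy optimum is not a posterior-mean composition; evaluate ",
         "E[S/(K_M+S)|m] with posterior_functional_quadrature() instead.",
         call. = FALSE)
  }
  check_grid(grid)
  S_eff <- pmax(posterior_mean(grid, prior, meas), 0)
  lev <- optimal_enzyme(spec, S_eff)
  new_strategy_table(
    tibble::tibble(readout = as.numeric(grid), enzyme_level = lev),
    meta = list(kind = "bayes", spec = spec, prior = prior, meas = meas,
                response = classify_response(spec$alpha, spec$gamma))
  )
}
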