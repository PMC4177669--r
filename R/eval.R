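# Closed-form strategy functions used for head-to-head fitness comparisons.
# Each returns an enzyme level given the readout history; the effective
# nutrient estimate is clamped at zero before the static optimum.
strategy_functions <- function(spec, env_model, meas, memory = FALSE) {
  is_markov <- inherits(env_model, "markov_env")
  prior <- if (is_markov) {
    gaussian_prior(env_model$mu, env_model$sigma_E)
  } else {
    env_model
  }
  mu0 <- prior_mean(prior)
  const_level <- optimal_enzyme(spec, max(mu0, 0))
  fns <- list(
    naive = function(m, ...) optimal_enzyme(spec, pmax(m, 0)),
    constitutive = function(m, ...) rep(const_level, length(m)),
    bayes = function(m, ...) {
      optimal_enzyme(spec, pmax(posterior_mean(m, prior, meas), 0))
    }
  )
  if (is_markov && memory) {
    fns$bayes_memory1 <- function(m, m_prev, ...) {
      optimal_enzyme(spec, pmax(posterior_mean_memory1(m, m_prev, env_model, meas), 0))
    }
    fns$bayes_memory2 <- function(m, m_prev, m_prev2, ...) {
      optimal_enzyme(
        spec,
        pmax(posterior_mean_memory2(m, m_prev, m_prev2, env_model, meas), 0)
      )
    }
  }
  fns
}

#' Build the reference strategy tables for a fitness comparison
#'
#' Tabulates, on one readout grid, the strategy families whose fitness the
#' framework compares: `naive` (treat the readout as the true nutrient level),
#' `constitutive` (ignore the readout; express at the optimum for the mean
#' environment), `bayes` (respond to the posterior mean), and for Markov
#' environments `bayes_memory1` (2-D in current and previous readout).
#'
#' @param spec A [payoff_spec()] with benefit linear in nutrient.
#' @param env_model A [gaussian_prior()], [mixture_prior()], or [markov_env()].
#' @param meas A [measurement_model()].
#' @param grid Strictly increasing readout grid.
#' @return Named list of [strategy_table] objects.
#' @export
build_reference_strategies <- function(spec, env_model, meas, grid) {
  check_grid(grid)
  fns <- strategy_functions(spec, env_model, meas,
                            memory = inherits(env_model, "markov_env"))
  out <- list()
  for (nm in c("naive", "constitutive", "bayes")) {
    out[[nm]] <- new_strategy_table(
      tibble::tibble(readout = as.numeric(grid),
                     enzyme_level = fns[[nm]](grid)),
      meta = list(kind = nm, spec = spec, env = env_model, meas = meas)
    )
  }
  if (inherits(env_model, "markov_env")) {
    out$bayes_memory1 <- dynamic_optimal_strategy(spec, env_model, meas, grid)
  }
  out
}

#' Monte-Carlo fitness comparison of strategy families
#'
#' Simulates one set of (S, m) draws (or one trajectory, for Markov
#' environments) and scores every reference strategy on it, so comparisons use
#' common random numbers and paired standard errors. Memory strategies are
#' included automatically for Markov environments.
#'
#' @param spec A [payoff_spec()] with benefit linear in nutrient.
#' @param env_model A [gaussian_prior()], [mixture_prior()], or [markov_env()].
#' @param meas A [measurement_model()].
#' @param n Number of Monte-Carlo pairs (>= 100).
#' @param seed Integer seed.
#' @param memory Include memory strategies (Markov environments only).
#' @return A `strategy_comparison` tibble with columns `strategy`,
#'   `mean_payoff`, `se`, `delta_vs_bayes` (paired difference bayes - this
#'   strategy), `delta_se` (paired SE of that difference); attributes carry
#'   the dimensionless parameters (beta, and lambda / xi where defined).
#' @examples
#' spec <- payoff_spec("linear", alpha = 2)
#' compare_strategies(spec, gaussian_prior(1, 0.5), measurement_model(0.5),
#'                    n = 1000, seed = 1)
#' @export
compare_strategies <- function(spec, env_model, meas, n, seed, memory = TRUE) {
  stopifnot(inherits(spec, "payoff_spec"), inherits(meas, "measurement_model"))
  if (n < 100) stop("Need n >= 100 for a meaningful standard error.", call. = FALSE)
  is_markov <- inherits(env_model, "markov_env")
  memory <- memory && is_markov
  fns <- strategy_functions(spec, env_model, meas, memory = memory)
  if (is_markov) {
    traj <- simulate_readouts(env_model, meas, n + 2L, seed)
    idx <- 3:(n + 2L)
    S <- traj$S[idx]
    args <- list(m = traj$m[idx], m_prev = traj$m[idx - 1L],
                 m_prev2 = traj$m[idx - 2L])
  } else {
    S <- sample_static(env_model, n, seed)
    args <- list(m = add_measurements(S, meas, seed))
  }
  payoffs <- lapply(fns, function(f) score_payoff(spec, do.call(f, args), S))
  d_bayes <- payoffs$bayes
  rows <- purrr::imap(payoffs, function(p, nm) {
    d <- d_bayes - p
    tibble::tibble(strategy = nm,
                   mean_payoff = mean(p),
                   se = stats::sd(p) / sqrt(n),
                   delta_vs_bayes = mean(d),
                   delta_se = stats::sd(d) / sqrt(n))
  })
  out <- dplyr::bind_rows(rows)
  params <- list(
    beta = beta_ratio(if (is_markov) gaussian_prior(env_model$mu, env_model$sigma_E)
                      else env_model, meas),
    lam = if (is_markov) env_model$lam else NA_real_,
    xi = if (inherits(env_model, "mixture_prior") &&
             length(env_model$weights) == 2L) xi_ratio(env_model, meas)
         else NA_real_,
    n = n, seed = seed
  )
  tibble::new_tibble(out, params = params, class = "strategy_comparison")
}

#' @export
print.strategy_comparison <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf("# strategy_comparison (beta = %.3g%s, n = %d)\n",
              p$beta,
              if (!is.na(p$lam)) sprintf(", lambda = %g", p$lam) else "",
              p$n))
  NextMethod()
}

#' Fitness value of retaining one measurement of memory
#'
#' Mean payoff of the memory-one Bayesian strategy minus that of the
#' memoryless Bayesian strategy, both evaluated on the same simulated
#' trajectory (common random numbers), with the paired Monte-Carlo standard
#' error. Memory is worthless when measurement is perfect (the current readout
#' already determines S) and when it is useless (both strategies collapse to
#' constitutive expression); it pays in between.
#'
#' @param spec A [payoff_spec()] with benefit linear in nutrient.
#' @param env A [markov_env()] with `lam` in (0, 1).
#' @param meas A [measurement_model()].
#' @param n Number of scored steps (>= 100).
#' @param seed Integer seed.
#' @return One-row tibble: `value` (payoff difference), `se` (paired SE),
#'   `beta`, `lam`, `n`.
#' @export
value_of_memory <- function(spec, env, meas, n, seed) {
  stopifnot(inherits(env, "markov_env"))
  if (env$lam <= 0) {
    stop("Memory has value only in a correlated environment (lam > 0).",
         call. = FALSE)
  }
  cmp <- compare_strategies(spec, env, meas, n, seed, memory = TRUE)
  mem <- cmp[cmp$strategy == "bayes_memory1", ]
  # delta_vs_bayes is bayes - memory1, so the value of memory is its negative
  tibble::tibble(value = -mem$delta_vs_bayes,
                 se = mem$delta_se,
                 beta = attr(cmp, "params")$beta,
                 lam = env$lam,
                 n = n)
}

#' Sweep the value of memory across measurement-noise levels
#'
#' @param spec A [payoff_spec()] with benefit linear in nutrient.
#' @param env A [markov_env()].
#' @param beta Vector of inverse signal-to-noise ratios to sweep;
#'   `sigma_m = sigma_E * sqrt(beta)`.
#' @param n Monte-Carlo steps per cell.
#' @param seed Integer seed (one independent sub-stream per cell).
#' @return Tibble with one row per beta: `beta`, `value`, `se`, `lam`, `n`.
#' @export
value_of_memory_sweep <- function(spec, env, beta = 10^seq(-2, 2), n = 1e5,
                                  seed = 1) {
  purrr::map_dfr(seq_along(beta), function(i) {
    meas <- measurement_model(env$sigma_E * sqrt(beta[i]))
    row <- value_of_memory(spec, env, meas, n, derive_seed(seed, i))
    row$beta <- beta[i]
    row[, c("beta", "value", "se", "lam", "n")]
  })
}

#' Map the best-performing strategy across noise (and persistence) regimes
#'
#' For every cell of a sweep over the inverse signal-to-noise ratio beta (and,
#' for Markov environments, the persistence lambda), runs a common-random-
#' numbers Monte-Carlo fitness comparison of the reference strategies and
#' reports the winner and its margins. Reproduces the qualitative regime
#' layout: naive wins (ties with bayes) at low noise, constitutive at high
#' noise, non-degenerate Bayesian inference in between.
#'
#' @param spec A [payoff_spec()] with benefit linear in nutrient.
#' @param env_model A [gaussian_prior()], [mixture_prior()], or [markov_env()];
#'   defines everything but the measurement noise, which the sweep sets as
#'   `sigma_m = sigma_E_total * sqrt(beta)`.
#' @param beta Vector of beta values to sweep.
#' @param lam Vector of persistence values (Markov environments only; default
#'   keeps the environment's own lambda).
#' @param n Monte-Carlo pairs per cell.
#' @param seed Integer seed.
#' @param memory Include memory strategies in Markov cells.
#' @return Tibble with one row per (beta, lam) cell: the dimensionless
#'   parameters, `winner`, `winner_payoff`, `margin_vs_bayes` (winner minus
#'   bayes, in paired SE units `margin_z`), and a nested `comparison` column.
#' @export
regime_map <- function(spec, env_model, beta = 10^seq(-3, 3, length.out = 5),
                       lam = NULL, n = 1e5, seed = 1, memory = TRUE) {
  is_markov <- inherits(env_model, "markov_env")
  if (!is_markov && !is.null(lam)) {
    stop("`lam` sweeps require a Markov environment.", call. = FALSE)
  }
  lam <- if (is_markov) (if (is.null(lam)) env_model$lam else lam) else NA_real_
  cells <- tidyr::expand_grid(beta = beta, lam = lam)
  cells$cell <- seq_len(nrow(cells))
  sd_tot <- if (is_markov) env_model$sigma_E else prior_sd_total(env_model)
  purrr::pmap_dfr(cells, function(beta, lam, cell) {
    em <- if (is_markov) markov_env(env_model$mu, env_model$sigma_E, lam)
          else env_model
    meas <- measurement_model(sd_tot * sqrt(beta))
    cmp <- compare_strategies(spec, em, meas, n, derive_seed(seed, cell),
                              memory = memory)
    best <- cmp[which.max(cmp$mean_payoff), ]
    tibble::tibble(
      beta = beta, lam = lam,
      xi = attr(cmp, "params")$xi,
      winner = best$strategy,
      winner_payoff = best$mean_payoff,
      margin_vs_bayes = -best$delta_vs_bayes,
      margin_z = ifelse(best$delta_se > 0,
                        -best$delta_vs_bayes / best$delta_se, 0),
      comparison = list(cmp)
    )
  })
}
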