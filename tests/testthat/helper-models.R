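# Shared model fixtures, built in code.

lin_spec <- function(alpha = 2, b = 1, c_cost = 1, E_max = Inf) {
  payoff_spec("linear", b = b, c_cost = c_cost, alpha = alpha, E_max = E_max)
}

mm_spec <- function(alpha = 2, K_M = 1, b = 1, c_cost = 1) {
  payoff_spec("michaelis_menten", b = b, K_M = K_M, c_cost = c_cost,
              alpha = alpha)
}

# Random parameter draws for property-style loops.
draw_gaussian_case <- function() {
  list(prior = gaussian_prior(mu = runif(1, -2, 2),
                              sigma_E = runif(1, 0.2, 2)),
       meas = measurement_model(runif(1, 0.05, 2)),
       m = runif(1, -3, 3))
}

draw_mixture_case <- function(k = sample(2:4, 1)) {
  w <- runif(k)
  list(prior = mixture_prior(weights = w / sum(w),
                             means = sort(runif(k, -3, 3)),
                             sds = runif(k, 0.2, 1.5)),
       meas = measurement_model(runif(1, 0.05, 1.5)),
       m = runif(1, -3, 3))
}

draw_markov_case <- function() {
  list(env = markov_env(mu = runif(1, -1, 1),
                        sigma_E = runif(1, 0.3, 2),
                        lam = runif(1, 0.05, 0.98)),
       meas = measurement_model(runif(1, 0.05, 2)))
}
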