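test_that("beta is the ratio of measurement to environmental variance", {
  expect_equal(beta_ratio(gaussian_prior(0, 1), measurement_model(0)), 0)
  expect_equal(beta_ratio(gaussian_prior(0, 1), measurement_model(1)), 1)
  expect_equal(beta_ratio(gaussian_prior(0, 0.1), measurement_model(1)), 100)
})

test_that("Gaussian posterior mean shrinks the readout toward the prior mean", {
  expect_equal(posterior_mean_gaussian(2, gaussian_prior(0, 1),
                                       measurement_model(0)), 2)
  expect_equal(posterior_mean_gaussian(2, gaussian_prior(0, 1),
                                       measurement_model(1)), 1)
  out <- posterior_mean_gaussian(1.7, gaussian_prior(0.3, 0.8),
                                 measurement_model(1.1), with_variance = TRUE)
  beta <- 1.1^2 / 0.8^2
  expect_equal(out$posterior_mean, (1.7 + beta * 0.3) / (1 + beta))
  expect_equal(out$posterior_var, 1.1^2 / (1 + beta))
})

test_that("uniform prior leaves the readout unchanged", {
  expect_equal(posterior_mean_uniform(0), 0)
  expect_equal(posterior_mean_uniform(3.2), 3.2)
  expect_equal(posterior_mean_uniform(-1), -1)
})

test_that("closed-form posterior means match quadrature across random draws", {
  set.seed(11)
  for (i in 1:60) {
    g <- draw_gaussian_case()
    cf <- posterior_mean_gaussian(g$m, g$prior, g$meas)
    quad <- posterior_mean_quadrature(g$m, prior_density(g$prior), g$meas,
                                      quadrature_bounds(g$prior, g$meas, g$m))
    expect_lt(abs(cf - quad), 1e-6)
  }
  for (i in 1:60) {
    mx <- draw_mixture_case()
    cf <- posterior_mean_mixture(mx$m, mx$prior, mx$meas)
    quad <- posterior_mean_quadrature(mx$m, prior_density(mx$prior), mx$meas,
                                      quadrature_bounds(mx$prior, mx$meas, mx$m))
    expect_lt(abs(cf - quad), 1e-6)
  }
})

test_that("mixture posterior mean has the right symmetry and special cases", {
  bp <- bimodal_prior(mu_bar = 0.7, delta_mu = 2, sigma_E = 0.2)
  ms <- measurement_model(0.5)
  # symmetry: midpoint readout returns the overall mean
  expect_equal(posterior_mean_mixture(0.7, bp, ms), 0.7)
  # single component reduces to the Gaussian closed form
  single <- mixture_prior(1, means = 0.3, sds = 0.8)
  expect_equal(posterior_mean_mixture(1.7, single, measurement_model(1.1)),
               posterior_mean_gaussian(1.7, gaussian_prior(0.3, 0.8),
                                       measurement_model(1.1)))
  # tanh form: responsibility difference matches the sigmoidal switch
  m <- seq(-2, 2, by = 0.1)
  beta <- ms$sigma_m^2 / 0.2^2
  mu_bar <- 0; dmu <- 2
  bp0 <- bimodal_prior(mu_bar, dmu, 0.2)
  expected <- (m + beta * mu_bar) / (1 + beta) +
    (beta / (1 + beta)) * (dmu / 2) *
      tanh((m - mu_bar) * dmu / (2 * (0.2^2 + ms$sigma_m^2)))
  expect_equal(posterior_mean_mixture(m, bp0, ms), expected, tolerance = 1e-12)
})

test_that("posterior means are monotone in the readout and bounded by shrinkage", {
  m <- seq(-6, 6, length.out = 400)
  set.seed(3)
  for (i in 1:20) {
    g <- draw_gaussian_case()
    pm <- posterior_mean_gaussian(m, g$prior, g$meas)
    expect_true(all(diff(pm) >= 0))
    expect_true(all(pmin(m, g$prior$mu) - 1e-12 <= pm &
                      pm <= pmax(m, g$prior$mu) + 1e-12))
    mx <- draw_mixture_case()
    expect_true(all(diff(posterior_mean_mixture(m, mx$prior, mx$meas)) >= -1e-10))
  }
})

test_that("xi measures mode distinguishability with the stated limits", {
  bp <- bimodal_prior(0, 2, 0.1)
  expect_equal(xi_ratio(bp, measurement_model(0)), 0)
  expect_equal(xi_ratio(bimodal_prior(0, 0, 0.1), measurement_model(0.5)), Inf)
  expect_equal(xi_ratio(bp, measurement_model(0.5)),
               0.25 / (2 * sqrt(0.26)))
  # swappable definition
  alt <- xi_ratio(bp, measurement_model(0.5),
                  fun = function(dmu, sE, sm) sm / dmu)
  expect_equal(alt, 0.25)
  expect_error(xi_ratio(mixture_prior(c(1/3, 1/3, 1/3), 1:3, rep(1, 3)),
                        measurement_model(1)), "bimodal")
})

test_that("bimodal posterior mean classifies at small xi and averages at large xi", {
  # distinguishable modes (sigma_E << sigma_m << delta_mu, xi << 1):
  # posterior mean ~ nearer mode mean away from the midpoint
  bp <- bimodal_prior(0, 2, sigma_E = 0.01)
  ms <- measurement_model(0.3)
  expect_lt(abs(posterior_mean_mixture(0.9, bp, ms) - 1), 0.01)
  expect_lt(abs(posterior_mean_mixture(-0.6, bp, ms) - (-1)), 0.01)
  # indistinguishable modes: posterior mean -> overall mean uniformly
  ms_big <- measurement_model(50)
  m <- seq(-3, 3, by = 0.5)
  expect_lt(max(abs(posterior_mean_mixture(m, bp, ms_big) - 0)), 0.01)
})

test_that("measurement regimes classify on order of magnitude", {
  expect_equal(classify_measurement_regime(1e-3, "unimodal"), "naive")
  expect_equal(classify_measurement_regime(1e3, "unimodal"), "constitutive")
  expect_equal(classify_measurement_regime(1, "unimodal"), "bayesian")
  expect_equal(classify_measurement_regime(1, "bimodal"), "ambiguous")
  expect_equal(classify_measurement_regime(1e-3, "bimodal"), "classification")
  expect_equal(classify_measurement_regime(c(0.01, 1, 100), "unimodal"),
               c("naive", "bayesian", "constitutive"))
})

test_that("noisy strategy composes the static optimum with the posterior mean", {
  spec <- lin_spec(alpha = 2)
  grid <- seq(-2, 4, by = 0.25)
  # sigma_m = 0 reduces to the perfect strategy (on the clamped readout)
  noiseless <- noisy_optimal_strategy(spec, gaussian_prior(1, 1),
                                      measurement_model(0), grid)
  perfect <- perfect_strategy(spec, grid)
  expect_equal(noiseless$enzyme_level, perfect$enzyme_level)
  # beta = 1 worked case: E*(m=3) with mu = 1 is ((3+1)/2)/2 = 1
  tab <- noisy_optimal_strategy(spec, gaussian_prior(1, 1),
                                measurement_model(1), grid)
  expect_equal(apply_strategy(tab, 3), 1)
  # constitutive limit: enormous beta pins every level at E*(mu)
  tab_inf <- noisy_optimal_strategy(spec, gaussian_prior(1, 1),
                                    measurement_model(1e6), grid)
  expect_lt(max(abs(tab_inf$enzyme_level - optimal_enzyme_graded(spec, 1))),
            1e-6)
  # concave cost: posterior mean thresholded against S_t
  spec_c <- lin_spec(alpha = 0.5, E_max = 4)
  tab_c <- noisy_optimal_strategy(spec_c, gaussian_prior(1, 1),
                                  measurement_model(1), grid)
  S_eff <- pmax(posterior_mean_gaussian(grid, gaussian_prior(1, 1),
                                        measurement_model(1)), 0)
  expect_equal(tab_c$enzyme_level, ifelse(S_eff > threshold_nutrient(spec_c), 4, 0))
  # Michaelis-Menten with noise is out of closed-form scope
  expect_error(noisy_optimal_strategy(mm_spec(), gaussian_prior(1, 1),
                                      measurement_model(1), grid),
               "posterior_functional_quadrature")
})

test_that("expected payoff under noise is maximized by the Bayes strategy", {
  spec <- lin_spec(alpha = 2)
  prior <- gaussian_prior(1, 0.7)
  meas <- measurement_model(0.7)
  grid <- seq(-3, 5, by = 0.05)
  refs <- build_reference_strategies(spec, prior, meas, grid)
  fits <- lapply(refs, expected_fitness_mc, env_model = prior, meas = meas,
                 spec = spec, n = 2e5, seed = 99)
  bayes <- fits$bayes
  for (nm in c("naive", "constitutive")) {
    margin <- bayes$mean_payoff - fits[[nm]]$mean_payoff
    se <- sqrt(bayes$se^2 + fits[[nm]]$se^2)
    expect_gt(margin, -3 * se)
  }
})
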