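test_that("reference strategies coincide in the appropriate limits", {
  spec <- lin_spec(alpha = 2)
  prior <- gaussian_prior(1, 1)
  grid <- seq(-2, 4, by = 0.25)
  # beta = 0: naive and bayes identical
  refs0 <- build_reference_strategies(spec, prior, measurement_model(0), grid)
  expect_equal(refs0$naive$enzyme_level, refs0$bayes$enzyme_level)
  # beta huge: bayes and constitutive identical within tolerance
  refs_inf <- build_reference_strategies(spec, prior, measurement_model(1e4),
                                         grid)
  expect_lt(max(abs(refs_inf$bayes$enzyme_level -
                      refs_inf$constitutive$enzyme_level)), 1e-6)
  # naive at m = mu equals the constitutive level
  refs <- build_reference_strategies(spec, prior, measurement_model(1), grid)
  expect_equal(apply_strategy(refs$naive, 1),
               refs$constitutive$enzyme_level[1])
  # markov environments add a 2-D memory table
  refs_m <- build_reference_strategies(spec, markov_env(1, 1, 0.9),
                                       measurement_model(1), grid)
  expect_true("bayes_memory1" %in% names(refs_m))
  expect_true(all(c("m_t", "m_prev") %in% names(refs_m$bayes_memory1)))
})

test_that("compare_strategies scores all families on common random numbers", {
  spec <- lin_spec(alpha = 2)
  cmp <- compare_strategies(spec, markov_env(1, 0.7, 0.9),
                            measurement_model(0.7), n = 5e4, seed = 3)
  expect_setequal(cmp$strategy, c("naive", "constitutive", "bayes",
                                  "bayes_memory1", "bayes_memory2"))
  expect_true(all(cmp$se >= 0))
  expect_equal(cmp$delta_vs_bayes[cmp$strategy == "bayes"], 0)
  # bayes (memoryless) beats naive and constitutive within paired MC error
  for (nm in c("naive", "constitutive")) {
    row <- cmp[cmp$strategy == nm, ]
    expect_gt(row$delta_vs_bayes, -3 * row$delta_se)
  }
  # memory variants beat memoryless bayes in a persistent noisy environment
  m1 <- cmp[cmp$strategy == "bayes_memory1", ]
  expect_gt(-m1$delta_vs_bayes, 3 * m1$delta_se)
  g <- glance(cmp)
  expect_true(g$winner %in% c("bayes_memory1", "bayes_memory2"))
})

test_that("memory is worthless at the noise extremes and valuable in between", {
  spec <- lin_spec(alpha = 2)
  env <- markov_env(1, 1, 0.9)
  # perfect measurement: exactly zero difference
  v0 <- value_of_memory(spec, env, measurement_model(0), n = 1e4, seed = 5)
  expect_equal(v0$value, 0)
  # intermediate noise: strictly positive
  v_mid <- value_of_memory(spec, env, measurement_model(1), n = 2e5, seed = 7)
  expect_gt(v_mid$value, 3 * v_mid$se)
  # overwhelming noise: negligible relative to the interior value (both
  # strategies are nearly constitutive, so the true advantage is O(1/beta^2))
  v_inf <- value_of_memory(spec, env, measurement_model(sqrt(1e3)),
                           n = 1e5, seed = 6)
  expect_lt(abs(v_inf$value), 0.02 * v_mid$value)
  expect_error(value_of_memory(spec, markov_env(1, 1, 0),
                               measurement_model(1), 1e4, 1), "lam > 0")
})

test_that("value of memory peaks at interior beta", {
  spec <- lin_spec(alpha = 2)
  env <- markov_env(1, 1, 0.9)
  sweep <- value_of_memory_sweep(spec, env, beta = 10^(-2:2), n = 2e5, seed = 9)
  expect_equal(nrow(sweep), 5)
  peak <- which.max(sweep$value)
  expect_true(peak %in% 2:4)
  # endpoints indistinguishable from zero relative to the peak
  expect_gt(sweep$value[peak], sweep$value[1] + 3 * sweep$se[peak])
  expect_gt(sweep$value[peak], sweep$value[5] + 3 * sweep$se[peak])
})

test_that("regime map reproduces the naive -> bayes -> constitutive layout", {
  spec <- lin_spec(alpha = 2)
  prior <- gaussian_prior(1, 1)
  map <- regime_map(spec, prior, beta = c(1e-3, 1, 1e3), n = 5e4, seed = 13)
  expect_equal(nrow(map), 3)
  # low noise: naive indistinguishable from bayes; high noise: constitutive.
  # ties are judged on the unpaired payoff SEs (paired SEs resolve the real
  # but negligible advantage bayes keeps at any finite beta)
  low <- map$comparison[[1]]
  naive_row <- low[low$strategy == "naive", ]
  bayes_low <- low[low$strategy == "bayes", ]
  expect_lt(abs(naive_row$mean_payoff - bayes_low$mean_payoff),
            3 * sqrt(naive_row$se^2 + bayes_low$se^2))
  high <- map$comparison[[3]]
  const_row <- high[high$strategy == "constitutive", ]
  bayes_high <- high[high$strategy == "bayes", ]
  expect_lt(abs(const_row$mean_payoff - bayes_high$mean_payoff),
            3 * sqrt(const_row$se^2 + bayes_high$se^2))
  # at intermediate noise bayes strictly beats both rivals
  mid <- map$comparison[[2]]
  for (nm in c("naive", "constitutive")) {
    row <- mid[mid$strategy == nm, ]
    expect_gt(row$delta_vs_bayes, 3 * row$delta_se)
  }
})

test_that("bimodal classification regime yields a near-step bayes strategy", {
  spec <- lin_spec(alpha = 2)
  bp <- bimodal_prior(mu_bar = 2, delta_mu = 2, sigma_E = 0.01)
  ms <- measurement_model(0.15) # sigma_E << sigma_m << delta_mu: xi ~ 0.075
  grid <- seq(0, 4, length.out = 201)
  tab <- noisy_optimal_strategy(spec, bp, ms, grid)
  lo <- optimal_enzyme_graded(spec, 1) # lower mode mean
  hi <- optimal_enzyme_graded(spec, 3) # upper mode mean
  near_mode <- abs(tab$enzyme_level - lo) < 0.05 * hi |
    abs(tab$enzyme_level - hi) < 0.05 * hi
  expect_gt(mean(near_mode), 0.95)
})

test_that("tidy, glance, and plots work on result objects", {
  spec <- lin_spec(alpha = 2)
  tab <- perfect_strategy(spec, grid = seq(0, 2, by = 0.5))
  expect_s3_class(tidy(tab), "tbl_df")
  expect_equal(glance(tab)$n_nodes, 5)
  expect_s3_class(autoplot(tab), "ggplot")
  tab2 <- dynamic_optimal_strategy(spec, markov_env(1, 1, 0.9),
                                   measurement_model(1), seq(-1, 3, by = 0.5))
  expect_s3_class(autoplot(tab2), "ggplot")
  cmp <- compare_strategies(spec, gaussian_prior(1, 1), measurement_model(1),
                            n = 1000, seed = 1)
  expect_s3_class(autoplot(cmp), "ggplot")
  expect_equal(nrow(glance(cmp)), 1)
  sweep <- value_of_memory_sweep(spec, markov_env(1, 1, 0.9),
                                 beta = c(0.1, 1), n = 1000, seed = 1)
  expect_s3_class(plot_memory_value(sweep), "ggplot")
  map <- regime_map(spec, gaussian_prior(1, 1), beta = c(0.01, 100),
                    n = 1000, seed = 1)
  expect_s3_class(plot_regime_map(map), "ggplot")
})
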