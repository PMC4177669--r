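Package: regstrat
Title: Optimal Enzyme Regulation Strategies Under Environmental Uncertainty
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-theoretic tools for computing optimal enzyme-regulation
    strategies given the statistics of a fluctuating nutrient environment,
    the precision of the cellular measurement apparatus, and the convexity of
    enzyme production costs relative to metabolic benefit. Provides closed-form
    Bayesian posterior-mean estimators for Gaussian, mixture, and mean-reverting
    Markov (AR(1)) environments, convexity-based classification of graded versus
    thresholded responses, Kalman-equivalent inference with one- and two-step
    measurement memory, a trajectory simulator, brute-force numerical oracles
    (adaptive quadrature, grid search, Monte-Carlo fitness), and head-to-head
    fitness comparison of naive, constitutive, Bayesian, and memory-based
    regulatory strategies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    yaml,
    generics,
    readr
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
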