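#' Classify the optimal response type from cost/benefit convexity
#'
#' With power-law cost \eqn{cE^\alpha} and benefit \eqn{bSE^\gamma}, the payoff
#' has a unique interior maximum (graded response) when cost is strictly convex
#' relative to benefit (\eqn{\alpha > \gamma}) and no interior maximum when
#' cost is strictly concave relative to benefit (\eqn{\alpha < \gamma}), in
#' which case the optimum sits on a boundary (thresholding between 0 and
#' `E_max`). At \eqn{\alpha = \gamma} the payoff is proportional to
#' \eqn{E^\gamma} and the optimum is a boundary point determined by the sign of
#' the linear coefficient (degenerate case).
#'
#' @param alpha Positive cost exponent.
#' @param gamma Positive benefit exponent in enzyme (1 for linear and
#'   Michaelis-Menten benefit).
#' @return `"graded"`, `"thresholding"`, or `"degenerate_linear"`.
#' @examples
#' classify_response(2, 1)    # convex cost: graded
#' classify_response(0.5, 1)  # concave cost: thresholding
#' @export
classify_response <- function(alpha, gamma = 1) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L,
            is.numeric(gamma), length(gamma) == 1L)
  if (alpha <= 0 || gamma <= 0) {
    stop("Exponents `alpha` and `gamma` must be positive.", call. = FALSE)
  }
  if (alpha > gamma) "graded" else if (alpha < gamma) "thresholding" else "degenerate_linear"
}

# Slope of the benefit in E at fixed S (valid for gamma = 1 modes).
benefit_slope <- function(spec, S) {
  switch(spec$benefit_mode,
    linear = spec$b * S,
    michaelis_menten = spec$b * S / (spec$K_M + S),
    power_law = spec$b * S # slope of E^gamma handled separately
  )
}

#' Optimal enzyme level: graded (convex-cost) regime
#'
#' The unique interior payoff maximizer in enzyme level, for cost strictly
#' convex relative to benefit (\eqn{\alpha > \gamma}), clamped to
#' `[0, E_max]`. For benefit linear in enzyme (slope \eqn{a(S)} in E),
#' \eqn{E^*(S) = (a(S) / (c\alpha))^{1/(\alpha-1)}}; for power-law benefit
#' \eqn{bSE^\gamma}, \eqn{E^*(S) = (\gamma b S / (\alpha c))^{1/(\alpha-\gamma)}}.
#'
#' @param spec A [payoff_spec()] with `alpha > gamma`.
#' @param S Non-negative nutrient level(s); vectorized.
#' @return Optimal enzyme level(s) in `[0, E_max]`.
#' @examples
#' spec <- payoff_spec("linear", b = 1, c_cost = 1, alpha = 2)
#' optimal_enzyme_graded(spec, S = 1)  # bS/(2c) = 0.5
#' @export
optimal_enzyme_graded <- function(spec, S) {
  stopifnot(inherits(spec, "payoff_spec"))
  if (spec$alpha <= spec$gamma) {
    stop("Graded optimum requires alpha > gamma (cost strictly convex ",
         "relative to benefit).", call. = FALSE)
  }
  check_nonneg(S, "S")
  E <- if (spec$benefit_mode == "power_law") {
    (spec$gamma * spec$b * S / (spec$alpha * spec$c_cost))^(1 / (spec$alpha - spec$gamma))
  } else {
    (benefit_slope(spec, S) / (spec$c_cost * spec$alpha))^(1 / (spec$alpha - 1))
  }
  pmin(E, spec$E_max)
}

#' Nutrient threshold for the switching (concave-cost) regime
#'
#' With cost concave relative to benefit the payoff at the upper boundary
#' changes sign at \eqn{S_t} solving \eqn{B(E_{max}, S_t) = C(E_{max})}. For
#' linear benefit \eqn{S_t = (c/b) E_{max}^{\alpha-1}}; for power-law benefit
#' \eqn{S_t = (c/b) E_{max}^{\alpha-\gamma}}; for Michaelis-Menten benefit the
#' hyperbola is inverted (returns `Inf` when even saturating nutrient cannot
#' pay for `E_max`).
#'
#' @param spec A [payoff_spec()] with finite `E_max` and `alpha <= gamma`.
#' @return The threshold nutrient concentration \eqn{S_t}.
#' @export
threshold_nutrient <- function(spec) {
  stopifnot(inherits(spec, "payoff_spec"))
  if (!is.finite(spec$E_max)) {
    stop("Thresholding requires a finite `E_max`.", call. = FALSE)
  }
  r <- spec$c_cost / spec$b * spec$E_max^(spec$alpha - spec$gamma)
  if (spec$benefit_mode == "michaelis_menten") {
    # solve b S/(K_M+S) = c E_max^{alpha-1}: S = K_M r / (1 - r)
    if (r >= 1) return(Inf)
    spec$K_M * r / (1 - r)
  } else {
    r
  }
}

#' Optimal enzyme level: thresholding (concave-cost) regime
#'
#' For cost concave relative to benefit (\eqn{\alpha \le \gamma}) the payoff
#' has no interior maximum, so the optimum is all-or-none: `E_max` when the
#' payoff at `E_max` is strictly positive (nutrient above the threshold
#' \eqn{S_t}), otherwise 0. At `S` exactly equal to the threshold both choices
#' pay 0 and the parsimonious choice of zero production is returned.
#'
#' @param spec A [payoff_spec()] with `alpha <= gamma` and finite `E_max`.
#' @param S Non-negative nutrient level(s); vectorized.
#' @return 0 or `E_max` for each `S`.
#' @export
optimal_enzyme_threshold <- function(spec, S) {
  stopifnot(inherits(spec, "payoff_spec"))
  if (spec$alpha > spec$gamma) {
    stop("Thresholding applies when alpha <= gamma; use optimal_enzyme_graded().",
         call. = FALSE)
  }
  check_nonneg(S, "S")
  S_t <- threshold_nutrient(spec)
  ifelse(S > S_t, spec$E_max, 0)
}

#' Optimal enzyme level at a known nutrient concentration
#'
#' Dispatches on [classify_response()]: the interior closed form in the graded
#' regime, boundary switching otherwise.
#'
#' @inheritParams optimal_enzyme_graded
#' @return Optimal enzyme level(s).
#' @export
optimal_enzyme <- function(spec, S) {
  cls <- classify_response(spec$alpha, spec$gamma)
  if (cls == "graded") optimal_enzyme_graded(spec, S)
  else optimal_enzyme_threshold(spec, S)
}

new_strategy_table <- function(df, meta) {
  stopifnot(is.data.frame(df))
  tibble::new_tibble(df, meta = meta, class = "strategy_table")
}

#' Strategy tables
#'
#' A strategy table is a tibble mapping readout value(s) to an enzyme level:
#' columns `readout` and `enzyme_level` (one-measurement strategies) or
#' `m_t`, `m_prev`, `enzyme_level` (memory-one strategies on a 2-D grid).
#' Consumers interpolate linearly (bilinearly for 2-D) between grid nodes and
#' clamp outside the grid. Provenance (payoff spec, prior, measurement model)
#' travels in `attr(x, "meta")`.
#'
#' @param x A `strategy_table`.
#' @name strategy_table
NULL

#' @export
print.strategy_table <- function(x, ...) {
  meta <- attr(x, "meta")
  cat("# A strategy_table", if (!is.null(meta$kind)) paste0("(", meta$kind, ")"), "\n")
  NextMethod()
}

#' Tabulate the optimal strategy under perfect measurement
#'
#' Computes the payoff-maximizing enzyme level at each readout value of a
#' grid, assuming the readout equals the true nutrient concentration.
#'
#' @param spec A [payoff_spec()].
#' @param grid Strictly increasing numeric vector of readout values.
#' @return A [strategy_table] with columns `readout`, `enzyme_level`.
#' @examples
#' spec <- payoff_spec("linear", alpha = 2)
#' perfect_strategy(spec, grid = c(0, 1, 2))
#' @export
perfect_strategy <- function(spec, grid) {
  check_grid(grid)
  lev <- optimal_enzyme(spec, pmax(grid, 0))
  new_strategy_table(
    tibble::tibble(readout = as.numeric(grid), enzyme_level = lev),
    meta = list(kind = "perfect", spec = spec,
                response = classify_response(spec$alpha, spec$gamma))
  )
}

check_grid <- function(grid) {
  stopifnot(is.numeric(grid), length(grid) >= 1L, all(is.finite(grid)))
  if (is.unsorted(grid, strictly = TRUE)) {
    stop("`grid` must be strictly increasing.", call. = FALSE)
  }
  invisible(grid)
}

#' Evaluate a strategy table at readout values
#'
#' Linear interpolation between grid nodes; readouts outside the grid clamp to
#' the edge levels. For 2-D (memory) tables, bilinear interpolation over
#' (`m_t`, `m_prev`).
#'
#' @param strategy A [strategy_table].
#' @param m Readout value(s); for 2-D tables a numeric matrix or data frame
#'   with columns `m_t` and `m_prev`.
#' @return Enzyme level(s).
#' @export
apply_strategy <- function(strategy, m) {
  stopifnot(inherits(strategy, "strategy_table"))
  if (all(c("m_t", "m_prev") %in% names(strategy))) {
    return(apply_strategy_2d(strategy, m))
  }
  if (nrow(strategy) == 1L) {
    return(rep(strategy$enzyme_level, length(m)))
  }
  stats::approx(strategy$readout, strategy$enzyme_level, xout = m,
                method = "linear", rule = 2)$y
}

apply_strategy_2d <- function(strategy, m) {
  if (is.data.frame(m)) m <- cbind(m$m_t, m$m_prev)
  if (is.null(dim(m))) m <- matrix(m, ncol = 2)
  gx <- sort(unique(strategy$m_t))
  gy <- sort(unique(strategy$m_prev))
  z <- matrix(NA_real_, length(gx), length(gy))
  z[cbind(match(strategy$m_t, gx), match(strategy$m_prev, gy))] <-
    strategy$enzyme_level
  x <- pmin(pmax(m[, 1], gx[1]), gx[length(gx)])
  y <- pmin(pmax(m[, 2], gy[1]), gy[length(gy)])
  ix <- pmin(pmax(findInterval(x, gx), 1L), length(gx) - 1L)
  iy <- pmin(pmax(findInterval(y, gy), 1L), length(gy) - 1L)
  tx <- (x - gx[ix]) / (gx[ix + 1L] - gx[ix])
  ty <- (y - gy[iy]) / (gy[iy + 1L] - gy[iy])
  z[cbind(ix, iy)] * (1 - tx) * (1 - ty) +
    z[cbind(ix + 1L, iy)] * tx * (1 - ty) +
    z[cbind(ix, iy + 1L)] * (1 - tx) * ty +
    z[cbind(ix + 1L, iy + 1L)] * tx * ty
}
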