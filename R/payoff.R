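#' Specify an enzyme cost/benefit (payoff) model
#'
#' A payoff spec bundles the benefit model for enzyme-catalyzed metabolism of
#' a nutrient together with a power-law production cost. Benefit is one of:
#'
#' * `"linear"`: \eqn{B(E, S) = b E S}, the unsaturated (low-nutrient) limit of
#'   Michaelis-Menten kinetics;
#' * `"michaelis_menten"`: \eqn{B(E, S) = b E S / (K_M + S)}, hyperbolic in
#'   nutrient, still linear in enzyme;
#' * `"power_law"`: \eqn{B(E, S) = b S E^\gamma}, used to study how the
#'   convexity of cost relative to benefit (in enzyme) selects graded versus
#'   thresholded regulation.
#'
#' Cost is always \eqn{C(E) = c E^\alpha}. The exponent `alpha` controls cost
#' convexity: `alpha > 1` is strictly convex, `alpha < 1` strictly concave.
#'
#' @param benefit_mode One of `"linear"`, `"michaelis_menten"`, `"power_law"`.
#' @param b Positive benefit rate coefficient (product per enzyme per nutrient
#'   per unit time).
#' @param K_M Positive Michaelis constant (nutrient-concentration units); used
#'   only by `"michaelis_menten"`.
#' @param c_cost Positive cost coefficient.
#' @param alpha Positive cost exponent.
#' @param gamma Positive benefit exponent in enzyme; must be 1 except for
#'   `"power_law"`.
#' @param E_max Maximal producible enzyme level; `Inf` is allowed (and the
#'   default) but concave-cost (thresholding) strategies require it finite.
#'
#' @return An object of class `payoff_spec`.
#' @examples
#' spec <- payoff_spec("linear", b = 1, c_cost = 1, alpha = 2)
#' payoff(spec, E = 0.5, S = 1)
#' @export
payoff_spec <- function(benefit_mode = c("linear", "michaelis_menten", "power_law"),
                        b = 1, K_M = 1, c_cost = 1, alpha = 2, gamma = 1,
                        E_max = Inf) {
  benefit_mode <- match.arg(benefit_mode)
  stopifnot(
    is.numeric(b), length(b) == 1L, b > 0,
    is.numeric(K_M), length(K_M) == 1L, K_M > 0,
    is.numeric(c_cost), length(c_cost) == 1L, c_cost > 0,
    is.numeric(alpha), length(alpha) == 1L, alpha > 0,
    is.numeric(gamma), length(gamma) == 1L, gamma > 0,
    is.numeric(E_max), length(E_max) == 1L, E_max > 0
  )
  if (benefit_mode != "power_law" && gamma != 1) {
    stop("`gamma` must be 1 for linear and michaelis_menten benefit modes.",
         call. = FALSE)
  }
  structure(
    list(benefit_mode = benefit_mode, b = b, K_M = K_M, c_cost = c_cost,
         alpha = alpha, gamma = gamma, E_max = E_max),
    class = "payoff_spec"
  )
}

#' @export
print.payoff_spec <- function(x, ...) {
  cat("<payoff_spec>\n")
  cat("  benefit:", x$benefit_mode,
      sprintf("(b = %g, K_M = %g, gamma = %g)\n", x$b, x$K_M, x$gamma))
  cat(sprintf("  cost:    c * E^alpha (c = %g, alpha = %g)\n", x$c_cost, x$alpha))
  cat(sprintf("  E_max:   %g\n", x$E_max))
  invisible(x)
}

check_nonneg <- function(x, name) {
  if (any(!is.finite(x) & !is.infinite(x))) {
    stop("`", name, "` must be numeric.", call. = FALSE)
  }
  if (any(x < 0)) stop("`", name, "` must be non-negative.", call. = FALSE)
  invisible(x)
}

#' Benefit of an enzyme level at a nutrient concentration
#'
#' Downstream product generated per unit time by enzyme-catalyzed metabolism.
#' Vectorized over `E` and `S` (recycled).
#'
#' @param spec A [payoff_spec()].
#' @param E Non-negative enzyme level(s).
#' @param S Non-negative nutrient concentration(s).
#' @return Numeric vector of benefit rates.
#' @export
benefit <- function(spec, E, S) {
  stopifnot(inherits(spec, "payoff_spec"))
  check_nonneg(E, "E")
  check_nonneg(S, "S")
  switch(spec$benefit_mode,
    linear = spec$b * E * S,
    michaelis_menten = spec$b * E * S / (spec$K_M + S),
    power_law = spec$b * S * E^spec$gamma
  )
}

#' Enzyme production cost
#'
#' Power-law cost \eqn{c E^\alpha} of maintaining an enzyme level.
#'
#' @inheritParams benefit
#' @return Numeric vector of costs.
#' @export
cost <- function(spec, E) {
  stopifnot(inherits(spec, "payoff_spec"))
  check_nonneg(E, "E")
  spec$c_cost * E^spec$alpha
}

#' Net payoff: benefit minus cost
#'
#' @inheritParams benefit
#' @return Numeric vector; may be negative when cost dominates.
#' @export
payoff <- function(spec, E, S) {
  benefit(spec, E, S) - cost(spec, E)
}

# Payoff used for Monte-Carlo fitness scoring. Gaussian environments assign
# mass to S < 0; benefits linear in S extend over the whole real line (a
# negative S simply scores as negative benefit, matching the model the
# closed-form strategies optimize). Michaelis-Menten clamps S at 0 since the
# hyperbola has a pole at -K_M.
score_payoff <- function(spec, E, S) {
  b <- switch(spec$benefit_mode,
    linear = spec$b * E * S,
    power_law = spec$b * S * E^spec$gamma,
    michaelis_menten = {
      Sp <- pmax(S, 0)
      spec$b * E * Sp / (spec$K_M + Sp)
    }
  )
  b - spec$c_cost * E^spec$alpha
}
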