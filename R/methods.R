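#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
tidy.strategy_table <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @export
glance.strategy_table <- function(x, ...) {
  meta <- attr(x, "meta")
  is_2d <- all(c("m_t", "m_prev") %in% names(x))
  tibble::tibble(
    kind = meta$kind %||% NA_character_,
    response = meta$response %||% NA_character_,
    dims = if (is_2d) 2L else 1L,
    n_nodes = nrow(x),
    min_level = min(x$enzyme_level),
    max_level = max(x$enzyme_level)
  )
}

#' @export
tidy.strategy_comparison <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @export
glance.strategy_comparison <- function(x, ...) {
  p <- attr(x, "params")
  best <- x[which.max(x$mean_payoff), ]
  tibble::tibble(
    winner = best$strategy,
    winner_payoff = best$mean_payoff,
    beta = p$beta, lam = p$lam, xi = p$xi, n = p$n
  )
}

#' Plot a strategy table
#'
#' One-measurement strategies plot as enzyme level versus readout;
#' memory-one strategies as a heat map over (current, previous) readout.
#'
#' @param object A [strategy_table].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.strategy_table <- function(object, ...) {
  meta <- attr(object, "meta")
  if (all(c("m_t", "m_prev") %in% names(object))) {
    ggplot2::ggplot(object, ggplot2::aes(x = .data$m_t, y = .data$m_prev,
                                         fill = .data$enzyme_level)) +
      ggplot2::geom_raster() +
      ggplot2::scale_fill_viridis_c(name = "enzyme level") +
      ggplot2::labs(x = "current readout", y = "previous readout",
                    title = meta$kind %||% "strategy") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(object, ggplot2::aes(x = .data$readout,
                                         y = .data$enzyme_level)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "readout", y = "optimal enzyme level",
                    title = meta$kind %||% "strategy") +
      ggplot2::theme_minimal()
  }
}

#' Plot a strategy fitness comparison
#'
#' @param object A `strategy_comparison` from [compare_strategies()].
#' @param ... Unused.
#' @return A ggplot of mean payoff with +/- 2 SE error bars per strategy.
#' @export
autoplot.strategy_comparison <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$strategy,
                                       y = .data$mean_payoff)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean_payoff - 2 * .data$se,
      ymax = .data$mean_payoff + 2 * .data$se)) +
    ggplot2::labs(x = NULL, y = "mean payoff") +
    ggplot2::theme_minimal()
}

#' Plot a value-of-memory sweep
#'
#' @param sweep Output of [value_of_memory_sweep()].
#' @return A ggplot of the memory fitness advantage versus beta (log scale).
#' @export
plot_memory_value <- function(sweep) {
  ggplot2::ggplot(sweep, ggplot2::aes(x = .data$beta, y = .data$value)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$value - 2 * .data$se,
                                      ymax = .data$value + 2 * .data$se),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression(beta ~ "(inverse SNR)"),
                  y = "fitness value of one-step memory") +
    ggplot2::theme_minimal()
}

#' Plot a regime map of winning strategies
#'
#' @param map Output of [regime_map()].
#' @return A ggplot tiling (beta, lambda) cells by winning strategy, or
#'   winner versus beta for static environments.
#' @export
plot_regime_map <- function(map) {
  if (all(is.na(map$lam))) {
    ggplot2::ggplot(map, ggplot2::aes(x = .data$beta, y = .data$winner)) +
      ggplot2::geom_point(size = 3) +
      ggplot2::scale_x_log10() +
      ggplot2::labs(x = expression(beta), y = "winning strategy") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(map, ggplot2::aes(x = factor(signif(.data$beta, 3)),
                                      y = factor(.data$lam),
                                      fill = .data$winner)) +
      ggplot2::geom_tile(color = "white") +
      ggplot2::labs(x = expression(beta), y = expression(lambda),
                    fill = "winner") +
      ggplot2::theme_minimal()
  }
}

#' @importFrom rlang .data
NULL
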