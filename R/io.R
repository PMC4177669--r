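# Config-block (de)serialization: model objects round-trip through plain
# named lists so they can live in YAML or JSON files.

as_config <- function(x) UseMethod("as_config")

#' @export
as_config.payoff_spec <- function(x) {
  list(type = "payoff_spec", benefit_mode = x$benefit_mode, b = x$b,
       K_M = x$K_M, c = x$c_cost, alpha = x$alpha, gamma = x$gamma,
       E_max = if (is.finite(x$E_max)) x$E_max else "inf")
}

#' @export
as_config.gaussian_prior <- function(x) {
  list(type = "gaussian_prior", mu = x$mu, sigma_E = x$sigma_E)
}

#' @export
as_config.mixture_prior <- function(x) {
  list(type = "mixture_prior", weights = x$weights, means = x$means,
       sds = x$sds)
}

#' @export
as_config.measurement_model <- function(x) {
  list(type = "measurement_model", sigma_m = x$sigma_m)
}

#' @export
as_config.markov_env <- function(x) {
  list(type = "markov_env", mu = x$mu, sigma_E = x$sigma_E, lam = x$lam)
}

from_config <- function(block) {
  stopifnot(is.list(block), !is.null(block$type))
  switch(block$type,
    payoff_spec = payoff_spec(
      benefit_mode = block$benefit_mode %||% "linear",
      b = block$b %||% 1, K_M = block$K_M %||% 1,
      c_cost = block$c %||% block$c_cost %||% 1,
      alpha = block$alpha %||% 2, gamma = block$gamma %||% 1,
      E_max = if (identical(block$E_max, "inf") || is.null(block$E_max)) Inf
              else block$E_max
    ),
    gaussian_prior = gaussian_prior(block$mu %||% 0, block$sigma_E %||% 1),
    mixture_prior = mixture_prior(unlist(block$weights), unlist(block$means),
                                  unlist(block$sds)),
    measurement_model = measurement_model(block$sigma_m %||% 0),
    markov_env = markov_env(block$mu %||% 0, block$sigma_E %||% 1,
                            block$lam %||% 0.9),
    stop("Unknown config block type: ", block$type, call. = FALSE)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a model configuration file
#'
#' Reads a YAML or JSON file whose top-level keys are named config blocks
#' (each with a `type` field: `payoff_spec`, `gaussian_prior`,
#' `mixture_prior`, `measurement_model`, `markov_env`) and reconstructs the
#' corresponding model objects.
#'
#' @param path File path; format chosen by extension (`.yaml`/`.yml`/`.json`).
#' @return Named list of model objects.
#' @export
read_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  lapply(raw, from_config)
}

#' Write model objects to a configuration file
#'
#' @param objects Named list of model objects ([payoff_spec()], priors,
#'   [measurement_model()], [markov_env()]).
#' @param path Output path; `.json` writes JSON, otherwise YAML.
#' @return `path`, invisibly.
#' @export
write_config <- function(objects, path) {
  blocks <- lapply(objects, as_config)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(blocks, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(blocks, path)
  }
  invisible(path)
}

#' Write a strategy table to CSV with a JSON metadata sidecar
#'
#' The table itself goes to `path` as plain CSV (`readout, enzyme_level` or
#' `m_t, m_prev, enzyme_level`); provenance (payoff spec, prior, measurement
#' model, environment) goes to `<path>.json`.
#'
#' @param strategy A [strategy_table].
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_strategy <- function(strategy, path) {
  stopifnot(inherits(strategy, "strategy_table"))
  readr::write_csv(tibble::as_tibble(strategy), path)
  meta <- attr(strategy, "meta")
  side <- list(kind = meta$kind %||% "unknown")
  for (field in c("spec", "prior", "meas", "env")) {
    if (!is.null(meta[[field]])) side[[field]] <- as_config(meta[[field]])
  }
  if (!is.null(meta$response)) side$response <- meta$response
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a strategy table written by [write_strategy()]
#'
#' @param path CSV path; the `<path>.json` sidecar is restored if present.
#' @return A [strategy_table].
#' @export
read_strategy <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  meta <- list()
  side_path <- paste0(path, ".json")
  if (file.exists(side_path)) {
    side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
    meta$kind <- side$kind
    for (field in c("spec", "prior", "meas", "env")) {
      if (!is.null(side[[field]])) meta[[field]] <- from_config(side[[field]])
    }
    meta$response <- side$response
  }
  new_strategy_table(df, meta = meta)
}
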