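# Run configuration: a single YAML file describing the model
# parameters, the founder cohorts, the stop criterion and the seed.
# Unknown keys are rejected loudly so that typos cannot silently fall
# back to defaults.

config_keys <- c("i_b", "i_d", "c", "p", "sigma", "lansing", "magnitude",
                 "founders", "max_events", "time_horizon", "seed")
founder_keys <- c("count", "x_b", "x_d", "lineage", "age")

#' Assemble a validated run configuration
#'
#' @param params A [bd_params()] object.
#' @param founders List of founder-cohort specs, each a list with `count`,
#'   `x_b`, `x_d` and optional `lineage` (default `"non_lansing"`) and
#'   `age` (default 0).
#' @param max_events,time_horizon Stop criteria; at least one finite.
#' @param seed Integer seed (mandatory).
#' @return An object of class `bd_run_config`.
#' @export
run_config <- function(params = bd_params(), founders,
                       max_events = Inf, time_horizon = Inf, seed) {
  stopifnot(inherits(params, "bd_params"))
  if (missing(seed) || is.null(seed)) {
    stop("config requires a `seed`", call. = FALSE)
  }
  if (!is.finite(max_events) && !is.finite(time_horizon)) {
    stop("config requires a finite `max_events` or `time_horizon`",
         call. = FALSE)
  }
  founders <- lapply(founders, validate_founder_spec)
  structure(list(params = params, founders = founders,
                 max_events = as.numeric(max_events),
                 time_horizon = as.numeric(time_horizon),
                 seed = as.integer(seed)),
            class = "bd_run_config")
}

validate_founder_spec <- function(f) {
  if (!is.list(f)) stop("each founder spec must be a mapping", call. = FALSE)
  unknown <- setdiff(names(f), founder_keys)
  if (length(unknown) > 0) {
    stop("unknown founder key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (k in c("count", "x_b", "x_d")) {
    if (is.null(f[[k]])) {
      stop(sprintf("founder spec is missing `%s`", k), call. = FALSE)
    }
  }
  if (f$count < 1) stop("founder `count` must be >= 1", call. = FALSE)
  f$count <- as.integer(f$count)
  f$x_b <- as.numeric(f$x_b)
  f$x_d <- as.numeric(f$x_d)
  f$lineage <- as_lineage(f$lineage %||% "non_lansing")
  f$age <- as.numeric(f$age %||% 0)
  if (f$age < 0) stop("founder `age` must be >= 0", call. = FALSE)
  f[founder_keys]
}

#' Read a run configuration from YAML
#'
#' Missing model parameters take the [bd_params()] defaults; `seed` and
#' a stop criterion are required; unknown keys and out-of-range values
#' are rejected with the offending key named.
#'
#' @param path Path to a YAML configuration file.
#' @return A `bd_run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), config_keys)
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(raw$founders)) stop("config is missing `founders`", call. = FALSE)
  if (is.null(raw$seed)) stop("config is missing `seed`", call. = FALSE)
  params <- bd_params(
    i_b = raw$i_b %||% 1, i_d = raw$i_d %||% 1, c = raw$c %||% 0,
    p = raw$p %||% 0, sigma = raw$sigma %||% 0,
    lansing = raw$lansing %||% FALSE, magnitude = raw$magnitude %||% 1
  )
  run_config(params, raw$founders,
             max_events = raw$max_events %||% Inf,
             time_horizon = raw$time_horizon %||% Inf,
             seed = raw$seed)
}

#' Write a run configuration to YAML
#'
#' The written file round-trips through [read_run_config()] to an
#' identical configuration.
#'
#' @param config A `bd_run_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "bd_run_config"))
  p <- config$params
  out <- list(i_b = p$i_b, i_d = p$i_d, c = p$c, p = p$p, sigma = p$sigma,
              lansing = p$lansing, magnitude = p$magnitude,
              founders = config$founders, seed = config$seed)
  if (is.finite(config$max_events)) out$max_events <- config$max_events
  if (is.finite(config$time_horizon)) out$time_horizon <- config$time_horizon
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' Execute a configured run and write its outputs
#'
#' Builds the founder cohorts, runs [simulate_bd()], and writes
#' `events.csv`, `final.csv`, the echoed `config.yaml` and a `VERSION`
#' stamp into `out_dir`. Floats are written in full precision so the
#' log replays exactly.
#'
#' @param config A `bd_run_config`.
#' @param out_dir Output directory (created if needed).
#' @return The `bd_sim`, invisibly.
#' @export
execute_run <- function(config, out_dir) {
  stopifnot(inherits(config, "bd_run_config"))
  founders <- dplyr::bind_rows(lapply(config$founders, function(f) {
    make_founders(f$count, f$x_b, f$x_d, f$lineage, f$age)
  }))
  sim <- simulate_bd(founders, config$params,
                     max_events = config$max_events,
                     time_horizon = config$time_horizon,
                     seed = config$seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_csv_full(sim$events, file.path(out_dir, "events.csv"))
  write_csv_full(sim$final, file.path(out_dir, "final.csv"))
  write_run_config(config, file.path(out_dir, "config.yaml"))
  writeLines(as.character(utils::packageVersion("agebd")),
             file.path(out_dir, "VERSION"))
  invisible(sim)
}

# CSV with shortest round-trip float representation
write_csv_full <- function(df, path) {
  out <- as.data.frame(df)
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      out[[j]] <- vapply(out[[j]], format, character(1), digits = 17)
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
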