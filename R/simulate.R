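#' Construct a founder cohort
#'
#' Builds the initial-population table consumed by [simulate_bd()]. By
#' default all founders are of age 0 at the start of the simulation
#' (`birth_time = 0`); older founders can be specified through `age`.
#'
#' @param n Number of founders.
#' @param x_b,x_d Trait values, recycled to length `n`.
#' @param lineage `"non_lansing"` or `"lansing"`, recycled.
#' @param age Founder ages at time 0 (>= 0), recycled.
#' @return A tibble with columns `x_b`, `x_d`, `lineage`, `birth_time`.
#' @export
make_founders <- function(n, x_b, x_d, lineage = "non_lansing", age = 0) {
  stopifnot(n >= 0)
  if (any(age < 0)) stop("founder `age` must be >= 0", call. = FALSE)
  tibble::tibble(
    x_b = rep_len(as.numeric(x_b), n),
    x_d = rep_len(as.numeric(x_d), n),
    lineage = as_lineage(rep_len(lineage, n)),
    birth_time = -rep_len(as.numeric(age), n)
  )
}

#' Founder cohorts with traits drawn uniformly at random
#'
#' Both genes of every founder are drawn independently and uniformly on
#' `range`, half the cohort in each lineage -- the mixed-population
#' starting condition of the branching-evolution experiment.
#'
#' @param n_per_lineage Founders per lineage.
#' @param range Length-2 interval for both genes.
#' @return A founder tibble (see [make_founders()]).
#' @export
uniform_founders <- function(n_per_lineage, range = c(-10, 10)) {
  stopifnot(length(range) == 2, all(is.finite(range)))
  n <- 2 * n_per_lineage
  tibble::tibble(
    x_b = stats::runif(n, range[1], range[2]),
    x_d = stats::runif(n, range[1], range[2]),
    lineage = rep(c("lansing", "non_lansing"), each = n_per_lineage),
    birth_time = 0
  )
}

#' Simulate the individual-based birth-death process
#'
#' Exact stochastic simulation (thinning / acceptance-rejection against
#' the per-individual bound `i_b + i_d + c (N - 1)`) of the
#' age-structured process defined by [bd_params()]: individuals give
#' birth at rate [birth_rate()], die at rate [death_rate()], offspring
#' traits pass through [mutate_traits()] and [apply_lansing()], ages
#' advance deterministically with the clock, and newborns have age
#' exactly 0 and their parent's lineage.
#'
#' @param founders Founder tibble (see [make_founders()]); columns
#'   `x_b`, `x_d` required, `lineage` (default `"non_lansing"`) and
#'   `birth_time` (default 0) optional. An empty table terminates
#'   immediately with reason `"extinction"`.
#' @param params A [bd_params()] object.
#' @param max_events Stop after this many accepted birth-or-death
#'   events (the event budget counts births plus deaths).
#' @param time_horizon Stop when the clock reaches this time.
#'   At least one of the two stop criteria must be finite and positive.
#' @param seed Integer RNG seed; mandatory, so every run is replayable.
#' @param record_events Keep the full event log (default). Disable for
#'   long runs where only the final population is needed.
#' @param sample_times Optional increasing vector of times at which to
#'   record cheap summaries of the living population (mean trait values,
#'   mean gap, per-lineage counts) without storing the full log.
#' @return An object of class `bd_sim`: a list with `events` (tibble:
#'   `time`, `kind`, `id`, `parent_id`, `x_b`, `x_d`, `lineage`),
#'   `founders`, `final` (individuals alive at termination),
#'   `termination` (`"event_budget"`, `"time_horizon"` or
#'   `"extinction"`), `time_end`, `n_events`, per-lineage birth/death
#'   counts, `seed` and `params`.
#' @examples
#' sim <- simulate_bd(make_founders(50, 1.5, 0.83),
#'                    bd_params(c = 0.01), time_horizon = 5, seed = 1)
#' glance(sim)
#' @export
simulate_bd <- function(founders, params = bd_params(),
                        max_events = Inf, time_horizon = Inf,
                        seed = NULL, record_events = TRUE,
                        sample_times = numeric(0)) {
  stopifnot(inherits(params, "bd_params"), is.data.frame(founders))
  if (is.null(seed)) {
    stop("`seed` is required: simulations must be explicitly seeded",
         call. = FALSE)
  }
  if (!is.finite(max_events) && !is.finite(time_horizon)) {
    stop("provide a finite `max_events` or `time_horizon`", call. = FALSE)
  }
  if (max_events < 0 || time_horizon < 0) {
    stop("stop criteria must be positive", call. = FALSE)
  }
  founders <- normalize_founders(founders)
  with_preserved_seed(seed, {
    raw <- sim_bd_cpp(
      founders$x_b, founders$x_d, founders$birth_time,
      match(founders$lineage, lineage_levels) - 1L,
      params$i_b, params$i_d, params$c, params$p, params$sigma,
      params$lansing, params$magnitude,
      max_events, time_horizon, record_events, 5e8,
      as.numeric(sort(sample_times))
    )
  })
  events <- NULL
  if (record_events) {
    events <- tibble::as_tibble(raw$events)
    events$kind <- c("birth", "death")[events$kind]
    events$lineage <- lineage_levels[events$lineage + 1L]
  }
  final <- tibble::tibble(
    id = raw$final_id, x_b = raw$final_x_b, x_d = raw$final_x_d,
    birth_time = raw$final_birth_time,
    lineage = lineage_levels[raw$final_lineage + 1L]
  )
  founders$id <- seq_len(nrow(founders))
  samples <- tibble::as_tibble(raw$samples)
  structure(
    list(events = events, founders = founders, final = final,
         samples = samples,
         termination = raw$termination, time_end = raw$time_end,
         n_events = raw$n_events, n_proposals = raw$n_proposals,
         births_by_lineage = stats::setNames(raw$births_by_lineage,
                                             lineage_levels),
         deaths_by_lineage = stats::setNames(raw$deaths_by_lineage,
                                             lineage_levels),
         seed = seed, params = params),
    class = "bd_sim"
  )
}

normalize_founders <- function(founders) {
  stopifnot(all(c("x_b", "x_d") %in% names(founders)))
  out <- tibble::as_tibble(founders)
  if (is.null(out$lineage)) out$lineage <- "non_lansing"
  out$lineage <- as_lineage(out$lineage)
  if (is.null(out$birth_time)) out$birth_time <- 0
  if (any(out$birth_time > 0)) {
    stop("founder `birth_time` must be <= 0 (age >= 0 at time 0)",
         call. = FALSE)
  }
  if (!all(is.finite(out$x_b) & (is.finite(out$x_d) | out$x_d == Inf))) {
    stop("founder traits must be finite (x_d may be +Inf: no hazard)",
         call. = FALSE)
  }
  out[c("x_b", "x_d", "lineage", "birth_time")]
}

# run `code` under `seed` without clobbering the caller's RNG state
with_preserved_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' @export
print.bd_sim <- function(x, ...) {
  cat("<bd_sim>\n")
  cat(sprintf("  founders : %d | events: %d | termination: %s @ t = %.4g\n",
              nrow(x$founders), as.integer(x$n_events), x$termination,
              x$time_end))
  n_lin <- table(factor(x$final$lineage, lineage_levels))
  cat(sprintf("  alive    : %d (non_lansing %d, lansing %d) | seed %s\n",
              nrow(x$final), n_lin[["non_lansing"]], n_lin[["lansing"]],
              format(x$seed)))
  invisible(x)
}

#' Individuals alive at a given time
#'
#' Exact reconstruction from the event log: an individual is alive at
#' `t` if it was born (or founded) at or before `t` and has no death
#' event at or before `t`.
#'
#' @param sim A `bd_sim` with a recorded event log.
#' @param t Time within `[0, time_end]`.
#' @return Tibble of living individuals (`id`, `x_b`, `x_d`,
#'   `birth_time`, `lineage`, `age`).
#' @export
snapshot_at <- function(sim, t) {
  stopifnot(inherits(sim, "bd_sim"))
  if (is.null(sim$events)) {
    stop("simulation was run with `record_events = FALSE`", call. = FALSE)
  }
  if (t < 0 || t > sim$time_end) {
    stop(sprintf("`t` must lie in [0, %.6g]", sim$time_end), call. = FALSE)
  }
  ev <- sim$events
  born <- dplyr::bind_rows(
    sim$founders[c("id", "x_b", "x_d", "birth_time", "lineage")],
    ev |>
      dplyr::filter(.data$kind == "birth", .data$time <= t) |>
      dplyr::transmute(id = .data$id, x_b = .data$x_b, x_d = .data$x_d,
                       birth_time = .data$time, lineage = .data$lineage)
  )
  dead <- ev$id[ev$kind == "death" & ev$time <= t]
  born |>
    dplyr::filter(!.data$id %in% dead) |>
    dplyr::mutate(age = t - .data$birth_time)
}

#' Per-lineage population-size trajectory
#'
#' Replays the event log into step-function counts of living
#' individuals per lineage over time.
#'
#' @param sim A `bd_sim` with a recorded event log.
#' @return Tibble with columns `time`, `lineage`, `n` (one row per
#'   event per lineage, starting from the founder counts at time 0).
#' @export
population_trajectory <- function(sim) {
  stopifnot(inherits(sim, "bd_sim"))
  if (is.null(sim$events)) {
    stop("simulation was run with `record_events = FALSE`", call. = FALSE)
  }
  purrr::map_dfr(lineage_levels, function(l) {
    n0 <- sum(sim$founders$lineage == l)
    ev <- sim$events[sim$events$lineage == l, ]
    delta <- ifelse(ev$kind == "birth", 1L, -1L)
    tibble::tibble(time = c(0, ev$time), lineage = l,
                   n = cumsum(c(n0, delta)))
  })
}
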