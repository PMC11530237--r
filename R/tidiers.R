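#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname simulate_bd
#' @param x A `bd_sim` object.
#' @param ... Unused.
#' @method tidy bd_sim
#' @export
tidy.bd_sim <- function(x, ...) {
  if (is.null(x$events)) {
    stop("simulation was run with `record_events = FALSE`", call. = FALSE)
  }
  x$events
}

#' @rdname simulate_bd
#' @method glance bd_sim
#' @export
glance.bd_sim <- function(x, ...) {
  fin <- table(factor(x$final$lineage, lineage_levels))
  tibble::tibble(
    n_founders = nrow(x$founders),
    n_events = as.numeric(x$n_events),
    time_end = x$time_end,
    termination = x$termination,
    n_final = nrow(x$final),
    n_final_non_lansing = as.integer(fin[["non_lansing"]]),
    n_final_lansing = as.integer(fin[["lansing"]]),
    births = sum(x$births_by_lineage),
    deaths = sum(x$deaths_by_lineage),
    seed = x$seed
  )
}

#' @rdname run_competition_cell
#' @param x A `bd_competition` object.
#' @param ... Unused.
#' @method tidy bd_competition
#' @export
tidy.bd_competition <- function(x, ...) x$replicates

#' @rdname run_competition_cell
#' @method glance bd_competition
#' @export
glance.bd_competition <- function(x, ...) x$summary

#' @rdname integrate_canonical
#' @param x A `bd_trajectory` object.
#' @param ... Unused.
#' @method glance bd_trajectory
#' @export
glance.bd_trajectory <- function(x, ...) {
  tibble::tibble(
    x_b_start = x$x_b[1], x_d_start = x$x_d[1],
    gap_limit = attr(x, "gap_limit"),
    gap_predicted = attr(x, "gap_predicted"),
    i_b = attr(x, "i_b"), i_d = attr(x, "i_d"),
    horizon = max(x$time)
  )
}

#' @rdname run_gap_convergence
#' @param x A `bd_gap_run` object.
#' @param ... Unused.
#' @method tidy bd_gap_run
#' @export
tidy.bd_gap_run <- function(x, ...) x$per_replicate

#' @rdname run_gap_convergence
#' @method glance bd_gap_run
#' @export
glance.bd_gap_run <- function(x, ...) {
  tibble::tibble(
    mean_gap = x$mean_gap,
    sd_gap = stats::sd(x$per_replicate$mean_gap),
    gap_predicted = asymptotic_gap(x$params$i_b, x$params$i_d),
    replicates = x$replicates,
    horizon = x$horizon,
    seed = x$seed
  )
}
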