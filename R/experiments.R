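# Scripted experiments: the Lansing vs non-Lansing competition grid,
# the Lansing-magnitude sweep, the uniform-trait branching run, the
# gap-convergence run, and decile summaries of simulation logs.

#' Founder cohorts for the matched-fitness competition experiment
#'
#' 500 Lansing founders at trait (1.5, 1.3) and 500 non-Lansing founders
#' at (1.5, 0.83) by default: the two traits have (approximately) equal
#' Malthusian parameters, so the competition starts fitness-neutral.
#' All founders are of age 0.
#'
#' @param n_per_lineage Founders per lineage.
#' @param trait_lansing,trait_non_lansing Length-2 trait vectors
#'   `c(x_b, x_d)`.
#' @return A founder tibble.
#' @export
competition_founders <- function(n_per_lineage = 500,
                                 trait_lansing = c(1.5, 1.3),
                                 trait_non_lansing = c(1.5, 0.83)) {
  dplyr::bind_rows(
    make_founders(n_per_lineage, trait_lansing[1], trait_lansing[2],
                  "lansing"),
    make_founders(n_per_lineage, trait_non_lansing[1],
                  trait_non_lansing[2], "non_lansing")
  )
}

#' Replicated Lansing vs non-Lansing competition
#'
#' Runs `replicates` independent mixed-population simulations (global
#' competition across both lineages) and summarizes them into the three
#' competition indexes: the ratio of collapsed populations, the pooled
#' progeny ratio, and the mean final Lansing share.
#'
#' A lineage "collapses" when it reaches 0 living individuals before the
#' stop criterion. `collapse_ratio` is the count of replicates in which
#' the Lansing lineage collapsed divided by the count in which the
#' non-Lansing lineage collapsed; when neither lineage ever collapses
#' the ratio is undefined (reported as `NA`, printed `"-"`).
#' `progeny_ratio` pools birth events over all replicates
#' (Lansing births / non-Lansing births). `lansing_share` is the mean
#' final Lansing fraction over replicates with at least one survivor.
#'
#' Before running, the founder traits are audited: each must be viable,
#' and when both lineages are present their Malthusian parameters
#' (lineage-specific) are compared -- a mismatch beyond `fitness_tol`
#' gives a warning, since the experiment is designed fitness-matched.
#'
#' @param founders Mixed founder tibble (default [competition_founders()]).
#' @param params [bd_params()]; `lansing` is forced on so that the
#'   Lansing lineage expresses its effect.
#' @param replicates Number of independent simulations.
#' @param max_events Birth-plus-death event budget per replicate.
#' @param seed Base seed; replicate `r` uses `seed + r`.
#' @param fitness_tol Tolerance for the founder fitness match audit.
#' @return An object of class `bd_competition` with per-replicate
#'   records (`tidy()`) and the summary indexes (`glance()`).
#' @export
run_competition_cell <- function(founders = competition_founders(),
                                 params = bd_params(c = 9e-4, p = 0.1,
                                                    sigma = 0.05,
                                                    lansing = TRUE),
                                 replicates = 20, max_events = 2e5,
                                 seed = NULL, fitness_tol = 0.01) {
  stopifnot(inherits(params, "bd_params"))
  if (replicates < 1) stop("`replicates` must be >= 1", call. = FALSE)
  if (!is.finite(max_events) || max_events <= 0) {
    stop("`max_events` must be a positive event budget", call. = FALSE)
  }
  if (is.null(seed)) stop("`seed` is required", call. = FALSE)
  params$lansing <- TRUE
  founders <- normalize_founders(founders)
  audit_founder_fitness(founders, params, fitness_tol)

  recs <- purrr::map_dfr(seq_len(replicates), function(r) {
    sim <- simulate_bd(founders, params, max_events = max_events,
                       seed = seed + r, record_events = FALSE)
    fin <- table(factor(sim$final$lineage, lineage_levels))
    tibble::tibble(
      replicate = r, seed = seed + r,
      termination = sim$termination, time_end = sim$time_end,
      births_lansing = sim$births_by_lineage[["lansing"]],
      births_non_lansing = sim$births_by_lineage[["non_lansing"]],
      final_lansing = as.integer(fin[["lansing"]]),
      final_non_lansing = as.integer(fin[["non_lansing"]]),
      collapsed_lansing = fin[["lansing"]] == 0L,
      collapsed_non_lansing = fin[["non_lansing"]] == 0L
    )
  })

  n_col_l <- sum(recs$collapsed_lansing)
  n_col_n <- sum(recs$collapsed_non_lansing)
  surv <- recs$final_lansing + recs$final_non_lansing > 0
  structure(
    list(
      replicates = recs,
      summary = tibble::tibble(
        n_replicates = replicates,
        collapses_lansing = n_col_l,
        collapses_non_lansing = n_col_n,
        collapse_ratio = if (n_col_l == 0 && n_col_n == 0) NA_real_
                         else n_col_l / n_col_n,
        progeny_ratio = sum(recs$births_lansing) /
                        sum(recs$births_non_lansing),
        lansing_share = mean(
          (recs$final_lansing /
             (recs$final_lansing + recs$final_non_lansing))[surv])
      ),
      params = params, max_events = max_events, seed = seed
    ),
    class = "bd_competition"
  )
}

audit_founder_fitness <- function(founders, params, tol) {
  key <- unique(founders[c("x_b", "x_d", "lineage")])
  lam <- purrr::pmap_dbl(key, function(x_b, x_d, lineage) {
    malthusian(tibble::tibble(x_b = x_b, x_d = x_d),
               params$i_b, params$i_d, lineage)$lambda
  })
  if (any(!is.finite(lam) | lam <= 0)) {
    stop("non-viable founder traits (lambda <= 0)", call. = FALSE)
  }
  both <- length(unique(key$lineage)) == 2
  if (both && (max(lam) - min(lam)) > tol) {
    warning(sprintf(
      "founder Malthusian parameters differ by %.3f (> %.3f): %s",
      max(lam) - min(lam), tol,
      "the competition is not fitness-matched"), call. = FALSE)
  }
  invisible(lam)
}

#' @export
print.bd_competition <- function(x, ...) {
  s <- x$summary
  cat("<bd_competition>", s$n_replicates, "replicates, budget",
      format(x$max_events, scientific = TRUE), "events\n")
  cr <- if (is.na(s$collapse_ratio)) "-" else sprintf("%.3f", s$collapse_ratio)
  cat(sprintf("  collapse ratio (L/nL) : %s  (%d vs %d collapses)\n",
              cr, s$collapses_lansing, s$collapses_non_lansing))
  cat(sprintf("  progeny ratio  (L/nL) : %.3f\n", s$progeny_ratio))
  cat(sprintf("  final Lansing share   : %.3f\n", s$lansing_share))
  invisible(x)
}

#' Sweep the magnitude of the Lansing effect
#'
#' Repeats the mixed competition at several Lansing magnitudes and
#' collects the final living individuals of every run, from which the
#' per-lineage distribution of the gap `x_b - x_d` at each magnitude can
#' be compared. At magnitude 0 the rule is inert; at magnitude 1
#' late-reproduction offspring are born with `x_d` exactly 0.
#'
#' @param magnitudes Numeric vector in `[0, 1]`.
#' @param founders Mixed founder tibble.
#' @param params [bd_params()] template (its `magnitude` is overridden).
#' @param replicates Replicates per magnitude.
#' @param max_events Event budget per replicate.
#' @param seed Base seed.
#' @return A tibble of final individuals with columns `magnitude`,
#'   `replicate`, `lineage`, `x_b`, `x_d`, `gap`.
#' @export
run_magnitude_sweep <- function(magnitudes = c(0, 0.5, 1),
                                founders = competition_founders(),
                                params = bd_params(c = 9e-4, p = 0.1,
                                                   sigma = 0.05,
                                                   lansing = TRUE),
                                replicates = 3, max_events = 2e5,
                                seed = NULL) {
  if (any(magnitudes < 0 | magnitudes > 1)) {
    stop("`magnitudes` must lie in [0, 1]", call. = FALSE)
  }
  if (is.null(seed)) stop("`seed` is required", call. = FALSE)
  founders <- normalize_founders(founders)
  purrr::map_dfr(seq_along(magnitudes), function(im) {
    m <- magnitudes[im]
    pars <- params; pars$lansing <- TRUE; pars$magnitude <- m
    purrr::map_dfr(seq_len(replicates), function(r) {
      sim <- simulate_bd(founders, pars, max_events = max_events,
                         seed = seed + (im - 1L) * replicates + r,
                         record_events = FALSE)
      dplyr::mutate(
        sim$final[c("lineage", "x_b", "x_d")],
        magnitude = m, replicate = r, gap = .data$x_b - .data$x_d,
        .before = 1)
    })
  })
}

#' Branching evolution from uniformly distributed traits
#'
#' Starts a mixed population whose founder genes are drawn independently
#' and uniformly on `range` (half Lansing, half non-Lansing), simulates
#' to `horizon`, and returns the per-lineage trait distribution among
#' individuals born in the terminal window `[horizon - window, horizon]`.
#' Extreme gaps are eliminated early; each lineage ends centered on its
#' own theoretical gap limit (0 for Lansing, `log(3)/2` for non-Lansing
#' at unit intensities).
#'
#' @param n_per_lineage Founders per lineage.
#' @param range Uniform range for both genes.
#' @param horizon Time horizon.
#' @param params [bd_params()].
#' @param seed RNG seed (draws the founders and drives the simulation).
#' @param window Width of the terminal birth window.
#' @return An object of class `bd_uniform_start`: list with `terminal`
#'   (tibble of individuals born in the window: `lineage`, `x_b`, `x_d`,
#'   `gap`, `birth_time`), `sim` (the full `bd_sim`) and `founders`.
#' @export
run_uniform_start <- function(n_per_lineage = 500, range = c(-10, 10),
                              horizon = 200,
                              params = bd_params(c = 9e-4, p = 0.1,
                                                 sigma = 0.05,
                                                 lansing = TRUE),
                              seed = NULL, window = 10) {
  if (is.null(seed)) stop("`seed` is required", call. = FALSE)
  if (!all(is.finite(range))) stop("`range` must be finite", call. = FALSE)
  founders <- with_preserved_seed(seed, uniform_founders(n_per_lineage, range))
  pars <- params; pars$lansing <- TRUE
  sim <- simulate_bd(founders, pars, time_horizon = horizon,
                     seed = seed + 1L, record_events = TRUE)
  births <- sim$events[sim$events$kind == "birth" &
                         sim$events$time >= horizon - window, ]
  terminal <- tibble::tibble(
    lineage = births$lineage, x_b = births$x_b, x_d = births$x_d,
    gap = births$x_b - births$x_d, birth_time = births$time
  )
  structure(list(terminal = terminal, sim = sim, founders = founders,
                 horizon = horizon, window = window),
            class = "bd_uniform_start")
}

#' @export
print.bd_uniform_start <- function(x, ...) {
  cat("<bd_uniform_start> horizon", x$horizon, "| terminal births:",
      nrow(x$terminal), "\n")
  s <- split(x$terminal$gap, x$terminal$lineage)
  for (l in names(s)) {
    cat(sprintf("  %-12s n = %5d, median gap %.3f\n",
                l, length(s[[l]]), stats::median(s[[l]])))
  }
  invisible(x)
}

#' Gap-convergence experiment
#'
#' Replicated individual-based runs from a monomorphic founder cohort,
#' tracking the population mean of `x_b - x_d` over time and averaging
#' it over the plateau window `[horizon / 2, horizon]`. With unit
#' intensities the plateau sits at the adaptive-dynamics limit
#' `log(3)/2 ~ 0.55` (finite traits and drift leave the desk-scale
#' estimate a little above it; averaging over replicates controls the
#' slow wander of the population mean).
#'
#' @param n_founders Founder count.
#' @param trait Length-2 founder trait `c(x_b, x_d)`.
#' @param params [bd_params()]; the published configuration uses
#'   `c = 9e-4`, `p = 0.1`, `sigma = 0.05`.
#' @param horizon Time horizon of each run.
#' @param replicates Number of independent runs.
#' @param seed Base seed; replicate `r` uses `seed + r`.
#' @param sample_by Sampling resolution of the mean-gap time series.
#' @return An object of class `bd_gap_run`: list with `mean_gap` (the
#'   replicate-averaged plateau estimate), `per_replicate` (tibble),
#'   `series` (tibble `time` x `replicate` mean-gap samples) and the
#'   configuration.
#' @export
run_gap_convergence <- function(n_founders = 1000, trait = c(1.2, 1.6),
                                params = bd_params(c = 9e-4, p = 0.1,
                                                   sigma = 0.05),
                                horizon = 1200, replicates = 50,
                                seed = NULL, sample_by = 10) {
  if (is.null(seed)) stop("`seed` is required", call. = FALSE)
  founders <- make_founders(n_founders, trait[1], trait[2])
  tgrid <- seq(0, horizon, by = sample_by)
  series <- purrr::map_dfr(seq_len(replicates), function(r) {
    sim <- simulate_bd(founders, params, time_horizon = horizon,
                       seed = seed + r, record_events = FALSE,
                       sample_times = tgrid)
    dplyr::mutate(sim$samples, replicate = r)
  })
  plateau <- series[series$time >= horizon / 2, ]
  per_rep <- plateau |>
    dplyr::group_by(.data$replicate) |>
    dplyr::summarise(mean_gap = mean(.data$mean_gap, na.rm = TRUE),
                     .groups = "drop")
  structure(
    list(mean_gap = mean(per_rep$mean_gap),
         per_replicate = per_rep, series = series,
         trait = trait, horizon = horizon, replicates = replicates,
         params = params, seed = seed),
    class = "bd_gap_run"
  )
}

#' @export
print.bd_gap_run <- function(x, ...) {
  cat(sprintf(
    "<bd_gap_run> %d replicates to t = %g | plateau mean gap %.3f (predicted %.3f)\n",
    x$replicates, x$horizon, x$mean_gap,
    asymptotic_gap(x$params$i_b, x$params$i_d)))
  invisible(x)
}

#' Decile curves of a per-individual statistic over time
#'
#' Reduces a simulation log to deciles 1, 5 and 9 of a per-individual
#' statistic per lineage along a time grid: `"gap"` (`x_b - x_d` of the
#' living), `"malthusian"` (each living individual's own
#' lineage-specific growth rate) or `"lifespan"` (realized death age
#' among individuals dead by each time). Empty cross-sections yield `NA`
#' rows rather than failing.
#'
#' @param sim A `bd_sim` with a recorded event log.
#' @param statistic One of `"gap"`, `"malthusian"`, `"lifespan"`.
#' @param times Time grid.
#' @return A tibble of class `bd_deciles`: `time`, `lineage`, `n`,
#'   `d1`, `d5`, `d9` (pointwise `d1 <= d5 <= d9`).
#' @export
summarize_deciles <- function(sim,
                              statistic = c("gap", "malthusian", "lifespan"),
                              times = NULL) {
  stopifnot(inherits(sim, "bd_sim"))
  statistic <- match.arg(statistic)
  if (is.null(sim$events)) {
    stop("simulation was run with `record_events = FALSE`", call. = FALSE)
  }
  if (is.null(times)) times <- seq(0, sim$time_end, length.out = 11)
  lam_cache <- new.env(parent = emptyenv())
  stat_values <- function(df, lin, t) {
    switch(statistic,
      gap = df$x_b - df$x_d,
      malthusian = purrr::pmap_dbl(df[c("x_b", "x_d")], function(x_b, x_d) {
        key <- paste(signif(x_b, 12), signif(x_d, 12), lin)
        if (is.null(lam_cache[[key]])) {
          lam_cache[[key]] <- malthusian_one(
            x_b, x_d, sim$params$i_b, sim$params$i_d, lin)$lambda
        }
        lam_cache[[key]]
      }),
      lifespan = df$lifespan
    )
  }
  deaths <- sim$events[sim$events$kind == "death", ]
  born_at <- c(stats::setNames(sim$founders$birth_time, sim$founders$id),
               with(sim$events[sim$events$kind == "birth", ],
                    stats::setNames(time, id)))
  deaths$lifespan <- deaths$time - born_at[as.character(deaths$id)]
  out <- purrr::map_dfr(times, function(t0) {
    purrr::map_dfr(lineage_levels, function(l) {
      if (statistic == "lifespan") {
        df <- deaths[deaths$time <= t0 & deaths$lineage == l, ]
      } else {
        snap <- snapshot_at(sim, t0)
        df <- snap[snap$lineage == l, ]
      }
      if (nrow(df) == 0) {
        return(tibble::tibble(time = t0, lineage = l, n = 0L,
                              d1 = NA_real_, d5 = NA_real_, d9 = NA_real_))
      }
      v <- stat_values(df, l, t0)
      q <- stats::quantile(v, c(0.1, 0.5, 0.9), names = FALSE, na.rm = TRUE)
      tibble::tibble(time = t0, lineage = l, n = nrow(df),
                     d1 = q[1], d5 = q[2], d9 = q[3])
    })
  })
  attr(out, "statistic") <- statistic
  class(out) <- c("bd_deciles", class(out))
  out
}
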