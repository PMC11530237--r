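test_that("degenerate simulations terminate as specified", {
  empty <- simulate_bd(make_founders(0, 1, 1), bd_params(),
                       time_horizon = 10, seed = 1)
  expect_equal(nrow(empty$final), 0)
  expect_equal(as.numeric(empty$n_events), 0)
  expect_identical(empty$termination, "extinction")

  # sterile, immortal, uncrowded: no active rate, clock runs out
  idle <- simulate_bd(make_founders(1, -1, Inf), bd_params(i_b = 1, i_d = 1),
                      time_horizon = 10, seed = 1)
  expect_equal(as.numeric(idle$n_events), 0)
  expect_identical(idle$termination, "time_horizon")
  expect_equal(idle$time_end, 10)

  expect_error(simulate_bd(make_founders(1, 1, 1), bd_params()),
               "seed")
  expect_error(simulate_bd(make_founders(1, 1, 1), bd_params(), seed = 1),
               "max_events")
})

test_that("runs are bit-identical under the same seed", {
  pars <- bd_params(c = 1e-3, p = 0.1, sigma = 0.05, lansing = TRUE)
  f <- dplyr::bind_rows(make_founders(25, 1.5, 1.3, "lansing"),
                        make_founders(25, 1.5, 0.83))
  a <- simulate_bd(f, pars, max_events = 5000, seed = 99)
  b <- simulate_bd(f, pars, max_events = 5000, seed = 99)
  expect_identical(a$events, b$events)
  expect_identical(a$final, b$final)
  c <- simulate_bd(f, pars, max_events = 5000, seed = 100)
  expect_false(identical(a$events, c$events))
})

test_that("event logs replay exactly: conservation and snapshots", {
  pars <- bd_params(c = 2e-3, p = 0.2, sigma = 0.1)
  sim <- simulate_bd(make_founders(40, 1.5, 0.83), pars,
                     max_events = 4000, seed = 17)
  ev <- sim$events
  expect_equal(nrow(sim$final),
               nrow(sim$founders) + sum(ev$kind == "birth") -
                 sum(ev$kind == "death"))
  # every death matches a prior birth or a founder
  known <- c(sim$founders$id, ev$id[ev$kind == "birth"])
  expect_true(all(ev$id[ev$kind == "death"] %in% known))
  expect_true(all(diff(ev$time) >= 0))

  expect_equal(nrow(snapshot_at(sim, 0)), nrow(sim$founders))
  for (t0 in c(0.5, 1.5, sim$time_end)) {
    snap <- snapshot_at(sim, t0)
    expect_equal(nrow(snap),
                 nrow(sim$founders) + sum(ev$kind == "birth" & ev$time <= t0) -
                   sum(ev$kind == "death" & ev$time <= t0))
    expect_true(all(snap$age >= 0))
  }
  expect_error(snapshot_at(sim, sim$time_end + 1), "\\[0, ")

  # a population driven extinct leaves an empty terminal snapshot
  dead <- simulate_bd(make_founders(5, -1, 0.5), bd_params(i_b = 0, i_d = 2),
                      time_horizon = 50, seed = 5)
  expect_identical(dead$termination, "extinction")
  expect_equal(nrow(snapshot_at(dead, dead$time_end)), 0)

  # population_trajectory agrees with snapshot counts
  tr <- population_trajectory(sim)
  n_at <- function(t0) {
    with(tr[tr$lineage == "non_lansing" & tr$time <= t0, ], n[length(n)])
  }
  expect_equal(n_at(1.5), nrow(snapshot_at(sim, 1.5)))
})

test_that("lifespans follow x_d + Exp(i_d) without competition", {
  sim <- simulate_bd(make_founders(4000, -1, 1.5),
                     bd_params(i_b = 0, i_d = 2),
                     time_horizon = 100, seed = 23)
  ages <- sim$events$time[sim$events$kind == "death"]  # founders born at 0
  expect_equal(length(ages), 4000)
  se <- stats::sd(ages) / sqrt(length(ages))
  expect_lt(abs(mean(ages) - (1.5 + 1 / 2)), 4 * se)
  expect_gte(min(ages), 1.5)  # no intrinsic deaths before the onset
  # the post-onset excess is exponential: sd = mean = 1/i_d
  expect_equal(stats::sd(ages - 1.5), 0.5, tolerance = 0.05)
})

test_that("logistic crowding settles at the mean-field equilibrium", {
  # hazard from birth, endless fertility: dN/dt = (i_b - i_d) N - c N^2
  sim <- simulate_bd(make_founders(200, 1e9, -1),
                     bd_params(i_b = 1, i_d = 0.5, c = 5e-4),
                     time_horizon = 60, seed = 42, record_events = FALSE,
                     sample_times = seq(30, 60, by = 0.5))
  n_bar <- mean(sim$samples$n_non_lansing)
  expect_equal(n_bar, (1 - 0.5) / 5e-4, tolerance = 0.05)
})

test_that("stochastic growth matches the Euler-Lotka rate for both lineages", {
  # rate measured over [5, 12] so the age-structure transient of the
  # age-0 founder cohort has decayed
  for (spec in list(list(trait = c(1.5, 0.83), lineage = "non_lansing"),
                    list(trait = c(1.5, 1.3), lineage = "lansing"))) {
    lam <- malthusian(tibble::tibble(x_b = spec$trait[1],
                                     x_d = spec$trait[2]),
                      lineage = spec$lineage)$lambda
    pars <- bd_params(lansing = spec$lineage == "lansing")
    rates <- sapply(1:4, function(r) {
      sim <- simulate_bd(
        make_founders(200, spec$trait[1], spec$trait[2], spec$lineage),
        pars, time_horizon = 13, seed = 300 + r,
        record_events = FALSE, sample_times = c(5, 12))
      n <- sim$samples$n_non_lansing + sim$samples$n_lansing
      log(n[2] / n[1]) / 7
    })
    se <- stats::sd(rates) / sqrt(length(rates))
    expect_lt(abs(mean(rates) - lam), 3 * se + 0.01)
  }
})

test_that("thinning agrees with a fine-time-step discretization oracle", {
  pars <- bd_params(i_b = 1, i_d = 1, c = 0.01)
  f <- make_founders(30, 1.5, 0.83)
  withr::with_seed(77, {
    disc <- replicate(10, {
      r <- oracle_discrete_sim(f, pars, horizon = 12, dt = 0.002)
      c(r$births, mean(r$death_ages))
    })
  })
  thin <- sapply(1:10, function(r) {
    sim <- simulate_bd(f, pars, time_horizon = 12, seed = 600 + r)
    d <- sim$events[sim$events$kind == "death", ]
    born <- c(stats::setNames(f$birth_time, seq_len(nrow(f))),
              with(sim$events[sim$events$kind == "birth", ],
                   stats::setNames(time, id)))
    c(sum(sim$events$kind == "birth"),
      mean(d$time - born[as.character(d$id)]))
  })
  # births per run and mean age at death agree within Monte-Carlo error
  se_b <- sqrt(stats::sd(disc[1, ])^2 + stats::sd(thin[1, ])^2) / sqrt(10)
  expect_lt(abs(mean(disc[1, ]) - mean(thin[1, ])), 4 * se_b)
  se_a <- sqrt(stats::sd(disc[2, ])^2 + stats::sd(thin[2, ])^2) / sqrt(10)
  expect_lt(abs(mean(disc[2, ]) - mean(thin[2, ])), 4 * se_a)
})

test_that("Lansing births carry exact zeros that propagate", {
  pars <- bd_params(c = 1e-3, p = 0.1, sigma = 0.05, lansing = TRUE)
  sim <- simulate_bd(make_founders(100, 1.5, 1.3, "lansing"), pars,
                     max_events = 2e4, seed = 8)
  births <- sim$events[sim$events$kind == "birth", ]
  zeros <- births[births$x_d == 0, ]
  expect_gt(nrow(zeros), 0)
  # children of exact-zero parents are exact zeros again (the override
  # re-applies: any reproducing zero parent has age > 0 = x_d)
  kids_of_zero <- births[births$parent_id %in% zeros$id, ]
  if (nrow(kids_of_zero) > 0) {
    expect_true(all(kids_of_zero$x_d == 0))
  }
})
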