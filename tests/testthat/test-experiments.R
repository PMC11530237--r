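test_that("competition audits its founders and rejects bad configs", {
  expect_error(run_competition_cell(replicates = 0, seed = 1),
               "replicates")
  expect_error(run_competition_cell(max_events = 0, seed = 1),
               "budget")
  expect_error(run_competition_cell(seed = NULL), "seed")
  expect_error(
    run_competition_cell(
      founders = dplyr::bind_rows(
        make_founders(5, 0.5, 0.5, "lansing"),     # i_b * x_b < 1
        make_founders(5, 1.5, 0.83)),
      replicates = 1, max_events = 100, seed = 1),
    "non-viable")
  expect_warning(
    run_competition_cell(
      founders = dplyr::bind_rows(
        make_founders(5, 3, 2.5, "lansing"),
        make_founders(5, 1.5, 0.83)),
      replicates = 1, max_events = 200, seed = 1),
    "fitness-matched")
})

test_that("competition summaries are internally consistent", {
  cc <- run_competition_cell(
    founders = competition_founders(60),
    replicates = 4, max_events = 2e4, seed = 11)
  recs <- tidy(cc)
  expect_equal(nrow(recs), 4)
  s <- glance(cc)
  expect_gte(s$progeny_ratio, 0)
  expect_true(is.na(s$lansing_share) ||
                (s$lansing_share >= 0 && s$lansing_share <= 1))
  expect_equal(s$collapses_lansing, sum(recs$collapsed_lansing))
  expect_equal(s$collapses_non_lansing, sum(recs$collapsed_non_lansing))
  if (s$collapses_lansing == 0 && s$collapses_non_lansing == 0) {
    expect_true(is.na(s$collapse_ratio))  # the "-" sentinel
  }
  expect_equal(s$progeny_ratio,
               sum(recs$births_lansing) / sum(recs$births_non_lansing))
  # replays identically
  cc2 <- run_competition_cell(
    founders = competition_founders(60),
    replicates = 4, max_events = 2e4, seed = 11)
  expect_identical(glance(cc), glance(cc2))
})

test_that("no lineage collapses under weak competition", {
  # scaled version of the lowest-competition grid row: capacity far
  # above the founding size, so the "-" sentinel appears
  cc <- run_competition_cell(
    founders = competition_founders(100),
    params = bd_params(c = 9e-5, p = 0.1, sigma = 0.05, lansing = TRUE),
    replicates = 3, max_events = 4e4, seed = 21)
  s <- glance(cc)
  expect_equal(s$collapses_lansing + s$collapses_non_lansing, 0)
  expect_true(is.na(s$collapse_ratio))
})

test_that("magnitude sweep spans the rule's endpoints", {
  expect_error(run_magnitude_sweep(magnitudes = c(-0.1, 1), seed = 1),
               "magnitudes")
  sw <- run_magnitude_sweep(
    magnitudes = c(0, 0.5, 1),
    founders = competition_founders(60),
    replicates = 2, max_events = 2e4, seed = 31)
  expect_setequal(unique(sw$magnitude), c(0, 0.5, 1))
  expect_equal(sw$gap, sw$x_b - sw$x_d)
  # magnitude 1 generates exact-zero onsets among the living
  expect_gt(sum(sw$x_d[sw$magnitude == 1 & sw$lineage == "lansing"] == 0), 0)
  # magnitude 0 never does (founding x_d = 1.3, mutations are continuous)
  expect_equal(sum(sw$x_d[sw$magnitude == 0] == 0), 0)
})

test_that("the sweep's evolved gap is insensitive to the magnitude", {
  sw <- run_magnitude_sweep(
    magnitudes = c(0, 0.5, 1),
    founders = competition_founders(150),
    replicates = 3, max_events = 1e5, seed = 41)
  gap_mode <- function(g) {
    d <- stats::density(g)
    d$x[which.max(d$y)]
  }
  # exclude exact-zero offspring (as the genotype comparison requires)
  lans <- sw[sw$lineage == "lansing" & (sw$x_d != 0 | sw$magnitude == 0), ]
  by_mag <- tapply(lans$gap, lans$magnitude, gap_mode)   # pooled per magnitude
  # across-replicate spread of the modal gap, from cells with enough
  # survivors to estimate a density (lineages can collapse in a replicate)
  modes <- lans |>
    dplyr::group_by(.data$magnitude, .data$replicate) |>
    dplyr::filter(dplyr::n() >= 50) |>
    dplyr::summarise(mode = gap_mode(.data$gap), .groups = "drop")
  spread_within <- stats::sd(modes$mode)
  expect_lt(max(by_mag) - min(by_mag), 3 * spread_within + 0.2)
})

test_that("uniform starts eliminate extreme positive gaps early", {
  us <- run_uniform_start(n_per_lineage = 300, horizon = 150, seed = 51)
  expect_s3_class(us$sim, "bd_sim")
  expect_true(all(us$terminal$birth_time >= 150 - 10))
  f0 <- mean(us$founders$x_b - us$founders$x_d > 4)
  snap <- snapshot_at(us$sim, 100)
  f100 <- mean(snap$x_b - snap$x_d > 4)
  expect_gt(f0, 0.2)          # extremes are common among founders
  expect_lt(f100, f0 / 2)     # and rare once selection has acted
})

test_that("decile curves are ordered and collapse for clones", {
  pars <- bd_params(c = 1e-3)
  clone <- simulate_bd(make_founders(80, 1.5, 0.83), pars,
                       max_events = 6000, seed = 61)
  dc <- summarize_deciles(clone, "gap", times = c(0, 1, 2))
  non <- dc[dc$lineage == "non_lansing", ]
  expect_true(all(non$d1 == non$d5 & non$d5 == non$d9))
  expect_equal(unique(non$d5), 1.5 - 0.83)
  # clone population: per-individual Malthusian deciles coincide too
  dm <- summarize_deciles(clone, "malthusian", times = c(1))
  expect_equal(dm$d5[dm$lineage == "non_lansing"], 0.4295017,
               tolerance = 1e-6)
  # absent lineage yields NA gaps, not an error
  expect_true(all(is.na(dc$d5[dc$lineage == "lansing"])))

  mut <- simulate_bd(make_founders(80, 1.5, 0.83),
                     bd_params(c = 1e-3, p = 0.3, sigma = 0.1),
                     max_events = 8000, seed = 62)
  dmut <- summarize_deciles(mut, "gap")
  ok <- !is.na(dmut$d5)
  expect_true(all(dmut$d1[ok] <= dmut$d5[ok] & dmut$d5[ok] <= dmut$d9[ok]))
  # realized lifespans: median near x_d + log(2)/i_d once deaths accrue
  dl <- summarize_deciles(mut, "lifespan", times = c(mut$time_end))
  expect_gt(dl$d5[dl$lineage == "non_lansing"], 0.83)
})

test_that("Lansing populations explore fitness space faster", {
  pars <- bd_params(c = 9e-4, p = 0.1, sigma = 0.05, lansing = TRUE)
  sim <- simulate_bd(competition_founders(300), pars,
                     max_events = 1.2e5, seed = 71)
  dc <- summarize_deciles(sim, "malthusian", times = seq(2, 10, by = 2))
  spread <- function(l) {
    rows <- dc[dc$lineage == l & !is.na(dc$d1), ]
    mean(rows$d9 - rows$d1)
  }
  expect_gte(spread("lansing"), spread("non_lansing"))
})
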