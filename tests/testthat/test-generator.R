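test_that("the emergence clock spaces ranks by one phyllochron", {
  cfg <- tiny_config(length_cv = 0, timing_sd = 0, treatments = NULL,
                     phyllochron = 2.3)
  tl <- simulate_tiller(cfg)
  phy <- tl$phytomers
  # nominal clock: offsets exactly one phyllochron apart
  expect_equal(diff(phy$offset), rep(2.3, nrow(phy) - 1))
  # true (height-model) emergence inherits the spacing away from the
  # decline boundary
  em <- phy$emergence_day[phy$rank %in% 11:16]
  expect_equal(diff(em), rep(2.3, length(em) - 1), tolerance = 0.02)
})

test_that("final lengths follow the plateau-then-decline rank profile", {
  cfg <- tiny_config(length_cv = 0, timing_sd = 0, treatments = NULL)
  phy <- simulate_tiller(cfg)$phytomers
  lp <- setNames(phy$final_length, phy$rank)
  # 20 % decline between rank 8 and rank 13
  expect_equal(unname(lp["13"] / lp["8"]), 0.80, tolerance = 1e-12)
  expect_equal(unname(lp["8"]), 100)
  expect_true(all(lp > 0))
})

test_that("true trajectories conserve component lengths exactly", {
  tl <- simulate_tiller(tiny_config(seed = 5, treatments = NULL))
  tr <- trajectory_table(tl)
  expect_equal(tr$blade + tr$sheath + tr$internode, tr$total, tolerance = 1e-12)
  # lengths never decrease in time
  for (r in unique(tr$rank)) {
    expect_true(all(diff(tr$total[tr$rank == r]) >= -1e-12))
  }
})

test_that("zero-noise tip emergence occurs near 26-27 % of final length", {
  # one tiller per treatment cell is enough: zero noise makes them identical
  cfg <- generator_config(n_tillers = 1, n_chambers = 1,
                          length_cv = 0, timing_sd = 0, seed = 1)
  exp <- generate_experiment(cfg)
  fe <- with(exp$truth, 1 / (1 + exp((1.82 - (emergence_day - offset)) / b)))
  fe <- fe[exp$truth$rank >= 10]
  expect_true(all(fe > 0.24 & fe < 0.29))
  expect_equal(mean(fe), 0.265, tolerance = 0.02)
})

test_that("observations are censored, gridded and non-negative", {
  obs <- fixture_noisy$observations
  truth <- fixture_noisy$truth
  expect_true(all(obs$distance >= 0))
  # every distance is a multiple of the 0.5 mm resolution
  expect_true(all(abs(obs$distance / 0.5 - round(obs$distance / 0.5)) < 1e-9))
  # censoring: no record before the phytomer's true emergence day
  first_day <- obs |>
    dplyr::group_by(tiller_id, rank) |>
    dplyr::summarise(first = min(day), .groups = "drop") |>
    dplyr::inner_join(truth, by = c("tiller_id", "rank"))
  expect_true(all(first_day$first >= first_day$emergence_day))
})

test_that("rounding of distances is half-up on the ruler grid", {
  expect_equal(phytodev:::round_to_resolution(12.24, 0.5), 12.0)
  expect_equal(phytodev:::round_to_resolution(12.25, 0.5), 12.5)
  expect_equal(phytodev:::round_to_resolution(12.74, 0.5), 12.5)
  # resolution 0 means an exact ruler
  expect_equal(phytodev:::round_to_resolution(12.24, 0), 12.24)
})

test_that("daily distance changes track true elongation", {
  tl <- simulate_tiller(tiny_config(length_cv = 0, timing_sd = 0,
                                    measurement_resolution = 0,
                                    treatments = NULL))
  obs <- emulate_observations(tl)
  tr <- trajectory_table(tl)
  cmp <- obs |>
    dplyr::inner_join(tr, by = c("day", "rank")) |>
    dplyr::arrange(rank, day) |>
    dplyr::group_by(rank, reference_rank) |>
    dplyr::mutate(dd = distance - dplyr::lag(distance),
                  dtrue = total - dplyr::lag(total)) |>
    dplyr::filter(!is.na(dd))
  # within a fixed reference ligule, measured change = true elongation
  expect_equal(cmp$dd, cmp$dtrue, tolerance = 1e-9)
})

test_that("a phytomer with no older visible ligule is measured from the base", {
  cfg <- tiny_config(rank_range = c(1, 4), observation_window = c(1, 8),
                     dissection_day = 8, length_cv = 0, timing_sd = 0,
                     measurement_resolution = 0, emergence_offset = 0,
                     treatments = NULL)
  tl <- simulate_tiller(cfg)
  obs <- emulate_observations(tl)
  tr <- trajectory_table(tl, days = 1:8)
  base_rows <- obs |>
    dplyr::filter(is.na(reference_rank)) |>
    dplyr::inner_join(tr, by = c("day", "rank"))
  expect_gt(nrow(base_rows), 0)
  expect_equal(base_rows$distance, base_rows$total, tolerance = 1e-9)
})

test_that("dissection applies the > 4 mm rule, rounding and maturity flags", {
  dis <- fixture_noisy$dissection
  expect_true(all(dis$phytomer_length > 4))
  expect_equal(dis$phytomer_length, dis$blade + dis$sheath + dis$internode)
  # mature records agree with true final length to within rounding of the
  # three components (1.5 resolution steps)
  cmp <- dis |>
    dplyr::filter(maturity == "mature") |>
    dplyr::inner_join(fixture_noisy$truth, by = c("tiller_id", "rank"))
  expect_true(all(abs(cmp$phytomer_length - cmp$final_length) <= 1.5))
  # about five immature phytomers per tiller at harvest
  n_imm <- dis |>
    dplyr::filter(maturity == "immature") |>
    dplyr::count(tiller_id)
  expect_true(all(n_imm$n >= 3 & n_imm$n <= 8))
  expect_equal(mean(n_imm$n), 5, tolerance = 0.3)
  expect_error(emulate_dissection(simulate_tiller(tiny_config(treatments = NULL)),
                                  day = 200),
               "outside")
})

test_that("identical seeds give identical experiments", {
  e1 <- generate_experiment(tiny_config(seed = 7))
  e2 <- generate_experiment(tiny_config(seed = 7))
  expect_identical(e1$observations, e2$observations)
  expect_identical(e1$dissection, e2$dissection)
  expect_identical(e1$truth, e2$truth)
  e3 <- generate_experiment(tiny_config(seed = 8))
  expect_false(identical(e1$observations, e3$observations))
})

test_that("the default experiment has the full factorial layout", {
  cfg <- generator_config()
  expect_equal(nrow(cfg$treatments), 4)
  expect_equal(cfg$n_tillers * cfg$n_chambers * nrow(cfg$treatments), 64)
  # config validation rejects impossible settings
  expect_error(generator_config(n_tillers = 0), "n_tillers")
  expect_error(generator_config(phyllochron = -1), "phyllochron")
  expect_error(generator_config(decline_per_rank = 0.2), "non-positive")
})

test_that("treatment phyllochron overrides propagate to the truth table", {
  truth <- fixture_noisy$truth
  sp <- truth |>
    dplyr::group_by(treatment, tiller_id) |>
    dplyr::summarise(p = mean(diff(offset)), .groups = "drop") |>
    dplyr::group_by(treatment) |>
    dplyr::summarise(p = mean(p))
  expected <- c(N1V1 = 2.4, N1V2 = 2.4, N2V1 = 2.1, N2V2 = 2.4)
  expect_equal(setNames(sp$p, sp$treatment), expected, tolerance = 0.05)
})
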