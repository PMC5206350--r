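mk_obs <- function(days, dists, tiller = "t1", rank = 12L) {
  tibble::tibble(tiller_id = tiller, rank = rank, day = days, distance = dists)
}

test_that("emergence lag is first distance over the initial elongation rate", {
  # 6 mm at first sight, 12 mm/day just after: the tip emerged half a day ago
  ev <- estimate_emergence(mk_obs(25:28, c(6, 18, 30, 42)))
  expect_equal(ev$rate, 12)
  expect_equal(ev$lag, 0.5)
  expect_equal(ev$emergence_day, 24.5)
  expect_true(ev$reliable)
  # tip caught exactly at emergence
  ev0 <- estimate_emergence(mk_obs(25:27, c(0, 12, 24)))
  expect_equal(ev0$lag, 0)
  expect_equal(ev0$emergence_day, 25)
  # a shrinking series cannot yield a lag: flagged, not dropped silently
  evbad <- estimate_emergence(mk_obs(25:27, c(6, 5, 4)))
  expect_false(evbad$reliable)
  expect_true(is.na(evbad$lag))
  # an implausibly long extrapolation is flagged unreliable
  evfar <- estimate_emergence(mk_obs(25:27, c(60, 62, 64)))
  expect_false(evfar$reliable)
})

test_that("phyllochron is the mean spacing of successive emergences", {
  ev <- estimate_emergence(dplyr::bind_rows(
    mk_obs(24:26, c(1, 13, 25), rank = 10L),
    mk_obs(26:28, c(0.6, 12.6, 24.6), rank = 11L),
    mk_obs(29:31, c(0.2, 12.2, 24.2), rank = 12L)
  ))
  expect_equal(compute_phyllochron(ev)$phyllochron,
               mean(diff(ev$emergence_day)))
  # hand-built events: 24.0, 26.3, 28.6 give exactly 2.3
  ev2 <- tibble::tibble(tiller_id = "t1", rank = 10:12,
                        emergence_day = c(24.0, 26.3, 28.6), reliable = TRUE)
  expect_equal(compute_phyllochron(ev2)$phyllochron, 2.3)
  # a missing middle rank is bridged by rank-gap normalization
  ev3 <- ev2[c(1, 3), ]
  expect_equal(compute_phyllochron(ev3)$phyllochron, 2.3)
  # a single event is undefined
  expect_warning(out <- compute_phyllochron(ev2[1, ]), "< 2")
  expect_true(is.na(out$phyllochron))
  expect_error(compute_phyllochron(ev2[0, ]), "no reliable")
})

test_that("full expansion is detected when the distance stops changing", {
  ser <- mk_obs(25:32, c(50, 70, 85, 91.5, 92, 92, 92, 92))
  cess <- detect_full_expansion(ser)
  expect_true(cess$mature)
  expect_equal(cess$cessation_day, 29)  # the first 92.0 day
  # a monotone rising series is immature
  rising <- mk_obs(25:30, c(10, 20, 30, 40, 50, 60))
  expect_false(detect_full_expansion(rising)$mature)
})

test_that("final length extrapolates the per-tiller rank line", {
  dis <- tibble::tibble(tiller_id = "t1", rank = 8:12,
                        phytomer_length = c(100, 96, 92, 88, 84),
                        maturity = "mature")
  # exact line: 100 mm at rank 8 falling 4 mm per rank -> 76 mm at rank 14
  expect_equal(predict_final_length(dis, 14), 76, tolerance = 1e-9)
  # a constant profile predicts itself anywhere
  dis$phytomer_length <- 90
  expect_equal(predict_final_length(dis, c(13, 16)), c(90, 90), tolerance = 1e-9)
  expect_error(predict_final_length(dis[1:2, ], 13), ">= 3 mature")
})

test_that("fraction of final length is the plain ratio with guards", {
  expect_equal(fraction_of_final(93, 93), 1)
  expect_equal(fraction_of_final(46.5, 93), 0.5)
  expect_error(fraction_of_final(10, 0), "> 0")
  expect_error(fraction_of_final(-1, 10), ">= 0")
})

test_that("mature phytomers get fraction exactly 1, immature below 1", {
  dis_f <- add_final_length_predictions(fixture_clean$dissection)
  expect_true(all(dis_f$f_L[dis_f$maturity == "mature"] == 1))
  expect_true(all(dis_f$f_L[dis_f$maturity == "immature"] < 1))
  # component fractions sum to the phytomer fraction
  expect_equal(dis_f$blade_f + dis_f$sheath_f + dis_f$internode_f, dis_f$f_L,
               tolerance = 1e-9)
})

test_that("the visible time course telescopes back from the final length", {
  # constant 10 mm/day increments ending at 100 mm: fractions step by 0.1
  obs <- mk_obs(25:32, c(5, 15, 25, 35, 45, 50, 50, 50))
  ev <- estimate_emergence(obs)
  cess <- detect_full_expansion(obs)
  dis <- tibble::tibble(tiller_id = "t1", rank = 12L,
                        phytomer_length = 100, maturity = "mature")
  tc <- build_visible_timecourse(obs, dis, ev, cess, ranks = 12L)
  expect_equal(tc$f_L, c(0.55, 0.65, 0.75, 0.85, 0.95, 1, 1, 1))
  expect_equal(tc$age, tc$day - ev$emergence_day)
  expect_true(all(tc$phase == "visible"))
})

test_that("invisible-phase ages come from anchor inversion plus phyllochron offsets", {
  crv <- timecourse_curve()
  dis_f <- tibble::tibble(
    tiller_id = "t1", rank = c(14L, 15L, 16L),
    f_L = c(0.70, 0.30, 0.10), maturity = "immature")
  out <- assign_invisible_ages(dis_f, crv, phyllochron = 2.3)
  # anchor at 0.70 sits at ~3.35 d; the next younger at 3.35 - 2.3
  a <- 1.82 + 1.81 * log(7 / 3)
  expect_equal(out$age, c(a, a - 2.3, a - 4.6), tolerance = 1e-9)
  # an anchor exactly at the midpoint maps to x0
  out2 <- assign_invisible_ages(
    tibble::tibble(tiller_id = "t1", rank = 15L, f_L = 0.5, maturity = "immature"),
    crv, phyllochron = 2.3, anchor_window = c(0.4, 0.8))
  expect_equal(out2$age, 1.82)
  # no candidate in the window: tiller skipped with a warning
  expect_warning(
    none <- assign_invisible_ages(
      tibble::tibble(tiller_id = "t1", rank = 15L, f_L = 0.95, maturity = "immature"),
      crv, phyllochron = 2.3),
    "anchor")
  expect_equal(nrow(none), 0)
})

test_that("reconstruction tracks the generator truth without noise", {
  exp <- fixture_exact
  recon <- quiet_recon(exp$observations, exp$dissection)
  truth <- exp$truth
  # emergence within half a day of the true crossing
  ev <- recon$events |>
    dplyr::filter(reliable) |>
    dplyr::inner_join(truth, by = c("tiller_id", "rank"), suffix = c("", ".t"))
  expect_lt(max(abs(ev$emergence_day - ev$emergence_day.t)), 0.5)
  # cessation of the monitored ranks within a day of the true 99 % crossing
  cess <- recon$cessation |>
    dplyr::filter(mature, rank %in% recon$monitored_ranks) |>
    dplyr::inner_join(truth, by = c("tiller_id", "rank"), suffix = c("", ".t"))
  expect_lt(max(abs(cess$cessation_day - cess$cessation_day.t)), 1)
  # reconstructed visible fractions within 0.01 of the true trajectory
  vis <- recon$visible |>
    dplyr::inner_join(truth, by = c("tiller_id", "rank")) |>
    dplyr::mutate(f_true = 1 / (1 + exp((1.82 - (day - offset)) / b)))
  expect_lt(max(abs(vis$f_L - vis$f_true)), 0.015)
  # invisible-phase ages within one phyllochron of truth
  ini <- recon$initial |>
    dplyr::inner_join(truth, by = c("tiller_id", "rank")) |>
    dplyr::mutate(age_true = 37 - emergence_day)
  expect_gt(nrow(ini), 0)
  expect_lt(max(abs(ini$age - ini$age_true)), 2.1)
})

test_that("visible and invisible ages agree where the phases overlap", {
  exp <- fixture_noisy
  recon <- quiet_recon(exp$observations, exp$dissection)
  truth <- exp$truth
  both <- dplyr::bind_rows(recon$visible, recon$initial) |>
    dplyr::inner_join(truth, by = c("tiller_id", "rank")) |>
    dplyr::mutate(age_true = ifelse(phase == "visible",
                                    day - emergence_day, 37 - emergence_day))
  agree <- both |>
    dplyr::group_by(phase) |>
    dplyr::summarise(bias = mean(age - age_true))
  expect_lt(max(abs(agree$bias)), 2.4)
})

test_that("coordination tables pair mature parents with immature successors", {
  dis_f <- add_final_length_predictions(fixture_clean$dissection)
  coord <- build_coordination_tables(dis_f)
  # a fully expanded P_n paired with an immature P_n+1 keeps f = 1 on the left
  mature_left <- coord$between |>
    dplyr::inner_join(dis_f |> dplyr::select(tiller_id, rank, maturity),
                      by = c("tiller_id", "rank_older" = "rank"))
  expect_true(all(mature_left$f_older[mature_left$maturity == "mature"] == 1))
  expect_true(all(coord$between$rank_younger == coord$between$rank_older + 1))
  # no sheath has been formed below half of final length
  young <- coord$within |> dplyr::filter(f_L < 0.45)
  expect_true(all(young$sheath_f == 0))
})

test_that("a young phytomer barely elongates before its parent reaches a quarter", {
  # the generator clock implies the between-phytomer censoring observed at
  # dissection: when P_n is at 25 %, P_n+1 is still tiny
  crv <- timecourse_curve()
  x_at_25 <- invert_sigmoid(crv, 0.25)
  for (p in c(2.1, 2.3, 2.4)) {
    expect_lt(eval_sigmoid(crv, x_at_25 - p), 0.15)
  }
})
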