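test_that("sigmoid evaluation matches the closed form and its anchors", {
  crv <- timecourse_curve()
  # midpoint is half the amplitude
  expect_equal(eval_sigmoid(crv, 1.82), 0.5)
  expect_equal(eval_sigmoid(sigmoid_curve(0.73, 0.37, 0.17), 0.37), 0.365)
  # two days after tip emergence the phytomer is at 52 % of final length
  expect_equal(round_half_up(100 * eval_sigmoid(crv, 2)), 52)
  # direct closed-form oracle
  expect_equal(eval_sigmoid(crv, 2), 1 / (1 + exp((1.82 - 2) / 1.81)))
  # invalid parameters are rejected at construction
  expect_error(sigmoid_curve(-1, 0, 1), "amplitude")
  expect_error(sigmoid_curve(1, 0, 0), "scale")
})

test_that("sigmoid inversion is the exact inverse", {
  crv <- timecourse_curve()
  expect_equal(invert_sigmoid(crv, 0.5), 1.82)
  # closed form: x0 + b log(7/3) at y = 0.7
  expect_equal(invert_sigmoid(crv, 0.7), 1.82 + 1.81 * log(7 / 3), tolerance = 1e-12)
  expect_error(invert_sigmoid(crv, 1.2), "out of range")
  expect_error(invert_sigmoid(crv, 0), "out of range")

  # invert . eval is the identity over +/- 18 scale units of every default
  # curve (further out the high tail saturates below double precision)
  for (crv in Filter(function(x) inherits(x, "sigmoid_curve"), coordination_rules())) {
    xs <- crv$x0 + crv$b * seq(-18, 18, length.out = 81)
    expect_equal(invert_sigmoid(crv, eval_sigmoid(crv, xs)), xs, tolerance = 1e-9)
  }
})

test_that("sigmoids are strictly monotone", {
  for (crv in Filter(function(x) inherits(x, "sigmoid_curve"), coordination_rules())) {
    # span +/- 15 scale units around the midpoint (beyond that the curve
    # saturates below double precision)
    xs <- crv$x0 + crv$b * seq(-15, 15, length.out = 400)
    expect_true(all(diff(eval_sigmoid(crv, xs)) > 0))
    expect_true(all(eval_sigmoid(crv, xs) > 0 & eval_sigmoid(crv, xs) < crv$a))
  }
})

test_that("component partition follows the piecewise rule and conserves length", {
  # pure blade below the sheath onset
  expect_equal(unlist(partition_components(0.25)[, -1]),
               c(blade = 0.25, sheath = 0, internode = 0))
  # at 75 % of final length: blade done at 66 %, sheath has contributed 9 %
  expect_equal(unlist(partition_components(0.75)[, -1]),
               c(blade = 0.66, sheath = 0.09, internode = 0))
  # full expansion: 66 / 14 / 20 and exact conservation
  full <- partition_components(1)
  expect_equal(unlist(full[, -1]), c(blade = 0.66, sheath = 0.14, internode = 0.20))

  f <- seq(0, 1, by = 1e-4)
  comp <- partition_components(f)
  expect_equal(comp$blade + comp$sheath + comp$internode, f, tolerance = 1e-12)
  expect_true(all(comp$blade >= 0 & comp$sheath >= -1e-12 & comp$internode >= 0))
  # continuity: no jumps anywhere on a fine grid
  for (col in c("blade", "sheath", "internode")) {
    expect_lt(max(abs(diff(comp[[col]]))), 1e-3)
  }
  expect_error(partition_components(1.2), "0, 1")
  expect_error(partition_thresholds(sheath_onset = 0.9), "invalid")
})

test_that("thermal time is linear degree-day accumulation", {
  # 37 d at 25 C above a 0 C base
  expect_equal(thermal_time(37, 25, 0), 925)
  # 13 d and 6 d above the 10.8 C base print as 185 and 85 degree days
  expect_equal(round_half_up(thermal_time(13, 25, 10.8)), 185)
  expect_equal(round_half_up(thermal_time(6, 25, 10.8)), 85)
  expect_equal(thermal_time(0, 25, 10.8), 0)
  # zero accumulation at or below the base temperature
  expect_equal(thermal_time(10, 10.8, 10.8), 0)
  expect_equal(thermal_time(10, 5, 10.8), 0)
  # linearity in duration
  expect_equal(thermal_time(14, 25, 10.8), 2 * thermal_time(7, 25, 10.8))
  expect_error(thermal_time(-1, 25, 0), ">= 0")
})

test_that("the default rule set carries the reference curve parameters", {
  rules <- coordination_rules()
  expect_equal(unlist(rules$blade), c(a = 0.73, x0 = 0.37, b = 0.17))
  expect_equal(unlist(rules$sheath), c(a = 0.46, x0 = 0.94, b = 0.13))
  expect_equal(unlist(rules$internode), c(slope = 0.04, intercept = -0.0063))
  expect_equal(unlist(rules$between), c(a = 1.34, x0 = 0.91, b = 0.24))
  expect_equal(unlist(rules$timecourse), c(a = 1, x0 = 1.82, b = 1.81))
})

test_that("curve parameter sets round-trip through JSON", {
  path <- withr::local_tempfile(fileext = ".json")
  rules <- coordination_rules()
  write_curves(rules, path)
  back <- read_curves(path)
  expect_equal(lapply(back, unclass), lapply(unclass(rules), unclass))
  expect_s3_class(back$timecourse, "sigmoid_curve")
  expect_equal(back$internode$slope, 0.04)
})
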