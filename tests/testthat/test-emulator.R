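test_that("no radiation means no assimilation and no yield", {
  w <- weather_1
  w$radn[] <- 0
  out <- run_emulator(midpoints, w, plan_w1)
  expect_equal(out$wagt, 0)
  expect_equal(out$yield, 0)
})

test_that("the emulator is bit-deterministic in its inputs", {
  p <- offset_params()
  a <- run_emulator(p, weather_1, plan_w1)
  b <- run_emulator(p, weather_1, plan_w1)
  expect_identical(a, b)
})

test_that("growth stages occur in strict order and are reported", {
  out <- run_emulator(midpoints, weather_1, plan_w1)
  expect_lt(out$day_jointing, out$day_flowering)
  expect_lte(out$day_flowering, out$day_grain_fill)
  expect_lt(out$day_grain_fill, out$day_maturity)
})

test_that("weather too short for the phenology is an error, not a clamp", {
  short <- weather_1[1:90, ]
  expect_error(run_emulator(midpoints, short, plan_w1), "maturity")
})

test_that("all parameter-bound corners reach maturity in a default season", {
  # slowest corner: all thermal-time targets at their upper bounds with
  # maximum photoperiod/vernalization delay
  slow <- midpoints
  slow[c("T1", "T2", "T3", "T4")] <- c(600, 800, 180, 900)
  slow[c("P4", "V1")] <- 5
  for (seed in 101:103) {
    w <- generate_weather(seed = seed)
    expect_no_error(run_emulator(slow, w, plan_w1))
  }
})

test_that("yield never exceeds aboveground biomass over random draws", {
  set.seed(10)
  U <- matrix(runif(1000 * 21), ncol = 21)
  out <- run_emulator_batch(U, list(weather_1), plan_w1)
  expect_true(all(is.finite(out)))
  expect_true(all(out[, "yield"] >= 0))
  expect_true(all(out[, "yield"] <= out[, "wagt"] + 1e-9))
})

test_that("more radiation-use efficiency never lowers biomass", {
  p <- midpoints
  hi <- p
  hi["R1"] <- min(p["R1"] * 1.1, specs_default$upper[specs_default$code == "R1"])
  base <- run_emulator(p, weather_1, plan_w1)
  up <- run_emulator(hi, weather_1, plan_w1)
  expect_gte(up$wagt, base$wagt)
})

test_that("wetter irrigation regimes never lower biomass at baseline", {
  # raising a phase's lower limit means irrigating sooner (more water)
  combos <- list(c("W5", "W1"),  # greening/jointing 50 -> 65
                 c("W1", "W4"),  # greening/jointing 65 -> 80
                 c("W2", "W1"),  # heading/grain fill 50 -> 65
                 c("W1", "W3"))  # heading/grain fill 65 -> 80
  for (cmb in combos) {
    dry <- run_emulator(midpoints, weather_1, ctx_small$plans[[cmb[1]]])
    wet <- run_emulator(midpoints, weather_1, ctx_small$plans[[cmb[2]]])
    expect_gte(wet$wagt, dry$wagt)
  }
})

test_that("reference demand is zero at zero forcing and monotone", {
  expect_equal(reference_demand(0, 0, 0), 0)
  d1 <- reference_demand(20, 8, 15)
  expect_gte(reference_demand(20, 8, 30), d1)   # more radiation
  expect_gte(reference_demand(28, 16, 15), d1)  # warmer
  expect_true(all(is.finite(
    reference_demand(weather_1$maxt, weather_1$mint, weather_1$radn))))
  expect_true(all(
    reference_demand(weather_1$maxt, weather_1$mint, weather_1$radn) >= 0))
})

test_that("the simulator adapter contract wraps the emulator", {
  ad <- simulator_adapter("bundled-emulator", function(params, weather, plan) {
    out <- run_emulator(params, weather, plan)
    list(wagt = out$wagt, yield = out$yield)
  })
  res <- ad$evaluate(midpoints, weather_1, plan_w1)
  ref <- run_emulator(midpoints, weather_1, plan_w1)
  expect_equal(res$wagt, ref$wagt)
  expect_equal(res$yield, ref$yield)
})

test_that("frozen tuning constants reproduce reference outputs", {
  # regression guard: the constant block ships frozen; any change to it or
  # to the daily loop shifts these values
  o <- run_emulator(midpoints, weather_1, plan_w1)
  expect_equal(o$wagt, 21623.8927, tolerance = 1e-7)
  expect_equal(o$yield, 2457.6424, tolerance = 1e-7)
  expect_equal(o$day_maturity, 295L)

  o2 <- run_emulator(offset_params(), weather_1, ctx_small$plans$W4)
  expect_equal(o2$wagt, 24195.4915, tolerance = 1e-7)
  expect_equal(o2$yield, 2702.3877, tolerance = 1e-7)
})
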