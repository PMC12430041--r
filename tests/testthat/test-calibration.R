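test_that("the Gaussian log-likelihood matches direct substitution", {
  obs <- generate_observations(midpoints, ctx_small, noise_sd = 0, seed = 1)
  # predictions == observations: the maximum, -M/2 log(2 pi sigma^2)
  M <- nrow(obs)
  expect_equal(log_likelihood(midpoints, obs, ctx_small, sigma_o = 250),
               -M / 2 * log(2 * pi * 250^2))

  # two-record hand case: O = (100, 200), P = (110, 190), sigma = 10
  obs2 <- obs[1:2, ]
  pred2 <- run_emulator_grid(midpoints, ctx_small, obs2)
  obs2$value <- pred2 + c(-10, 10)
  expect_equal(log_likelihood(midpoints, obs2, ctx_small, sigma_o = 10),
               2 * (-0.5 * log(2 * pi * 100)) - 1.0)

  # doubling a residual from r to 2r costs 3 r^2 / (2 sigma^2)
  obs3 <- obs[1, , drop = FALSE]
  pred3 <- run_emulator_grid(midpoints, ctx_small, obs3)
  obs3$value <- pred3 + 50
  l1 <- log_likelihood(midpoints, obs3, ctx_small, sigma_o = 100)
  obs3$value <- pred3 + 100
  l2 <- log_likelihood(midpoints, obs3, ctx_small, sigma_o = 100)
  expect_equal(l1 - l2, 3 * 50^2 / (2 * 100^2))

  expect_error(log_likelihood(midpoints, obs, ctx_small, sigma_o = 0),
               "sigma_o")
  expect_error(log_likelihood(midpoints, obs[0, ], ctx_small, 100),
               "no observations")
})

test_that("chains are deterministic in the seed and respect bounds", {
  obs <- generate_observations(offset_params(), ctx_small,
                               noise_sd = 300, seed = 2)
  cfg <- mcmc_config(n_iter = 300, seed = 77)
  ch1 <- run_mcmc(cfg, obs, ctx_small)
  ch2 <- run_mcmc(cfg, obs, ctx_small)
  expect_identical(ch1$draws, ch2$draws)
  expect_gt(ch1$acceptance_rate, 0)
  expect_lt(ch1$acceptance_rate, 1)
  specs <- ctx_small$specs
  for (code in colnames(ch1$draws)) {
    lo <- specs$lower[specs$code == code]
    hi <- specs$upper[specs$code == code]
    expect_true(all(ch1$draws[, code] >= lo & ch1$draws[, code] <= hi))
  }
})

test_that("pinned parameters stay bit-constant through the chain", {
  obs <- generate_observations(offset_params(), ctx_small,
                               noise_sd = 300, seed = 2)
  cfg <- mcmc_config(free = c("G1", "P1"), n_iter = 200, seed = 3)
  ch <- run_mcmc(cfg, obs, ctx_small)
  expect_setequal(colnames(ch$draws), c("G1", "P1"))
  expect_equal(ch$pinned[["T1"]], midpoints[["T1"]])
})

test_that("a flat likelihood recovers the uniform prior", {
  # constant-output simulator context: zero-variance likelihood surface
  obs <- data.frame(treatment = "W1", year = 1, variable = "yield",
                    value = 0)
  flat_ctx <- ctx_small
  # with sigma huge the likelihood is effectively flat over the prior
  cfg <- mcmc_config(free = c("K", "E1"), n_iter = 20000,
                     proposal_scale = 0.25, sigma_o = 1e9, seed = 5)
  ch <- run_mcmc(cfg, obs, flat_ctx)
  u <- sweep(sweep(ch$draws, 2, c(0, 0.75), `-`), 2, c(1, 1.5), `/`)
  thin <- u[seq(1, nrow(u), by = 10), ]
  for (j in 1:2) {
    ks <- suppressWarnings(stats::ks.test(thin[, j], "punif"))
    expect_lt(unname(ks$statistic), 0.08)
  }
  expect_gt(min(u), 0.0 - 1e-9)
  expect_lt(max(u), 1.0 + 1e-9)
})

test_that("point estimates follow the chain", {
  obs <- generate_observations(offset_params(), ctx_small,
                               noise_sd = 300, seed = 2)
  cfg <- mcmc_config(free = c("G1", "T3"), n_iter = 400, seed = 11)
  ch <- run_mcmc(cfg, obs, ctx_small)
  pm <- posterior_point_estimate(ch, "mean")
  expect_equal(pm[["G1"]], mean(ch$draws[, "G1"]))
  map <- posterior_point_estimate(ch, "map")
  i <- which.max(ch$log_post)
  expect_equal(map[["G1"]], unname(ch$draws[i, "G1"]))
  # degenerate chain: all draws equal -> that draw
  ch$draws <- ch$draws[rep(1, 10), ]
  ch$log_post <- rep(ch$log_post[1], 10)
  expect_equal(posterior_point_estimate(ch, "mean")[["T3"]],
               unname(ch$draws[1, "T3"]))
})

test_that("chains export as delimited text", {
  obs <- generate_observations(offset_params(), ctx_small,
                               noise_sd = 300, seed = 2)
  ch <- run_mcmc(mcmc_config(free = "G1", n_iter = 100, seed = 1),
                 obs, ctx_small)
  f <- withr::local_tempfile(fileext = ".csv")
  write_chain(ch, f)
  back <- utils::read.csv(f)
  expect_equal(back$G1, unname(ch$draws[, "G1"]))
  expect_equal(back$log_post, ch$log_post)
})

test_that("1-D Metropolis matches a known Gaussian target", {
  # detailed-balance smoke test on a closed-form posterior: single free
  # parameter, single observation, linear-enough response locally
  obs <- generate_observations(midpoints, ctx_small, noise_sd = 0, seed = 1)
  obs <- obs[obs$treatment == "W1" & obs$year == 1, , drop = FALSE]
  cfg <- mcmc_config(free = "G1", n_iter = 8000, burn_frac = 0.2,
                     proposal_scale = 0.1, sigma_o = 400, seed = 13)
  ch <- run_mcmc(cfg, obs, ctx_small)
  # the posterior concentrates near the generating value (the midpoint)
  expect_lt(abs(mean(ch$draws[, "G1"]) - midpoints[["G1"]]), 4)
  expect_true(stats::quantile(ch$draws[, "G1"], 0.025) < midpoints[["G1"]])
  expect_true(stats::quantile(ch$draws[, "G1"], 0.975) > midpoints[["G1"]])
})
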