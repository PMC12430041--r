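test_that("trajectory designs satisfy the one-at-a-time structure", {
  d <- build_trajectories(n = 5, p = 4, t = 6, seed = 2)
  expect_equal(d$delta, 4 / (2 * 3))
  expect_equal(nrow(d$points), 6 * 6)
  expect_true(all(d$points >= 0 & d$points <= 1))
  for (k in seq_len(d$t)) {
    rows <- (k - 1) * (d$n + 1) + seq_len(d$n + 1)
    pts <- d$points[rows, ]
    moved <- integer(0)
    for (j in seq_len(d$n)) {
      df <- abs(pts[j + 1, ] - pts[j, ])
      idx <- which(df > 1e-12)
      expect_length(idx, 1)                      # one coordinate per move
      expect_equal(df[idx], d$delta, tolerance = 1e-12)
      moved <- c(moved, idx)
    }
    expect_setequal(moved, seq_len(d$n))         # every factor once
  }
})

test_that("design arithmetic matches t * (n + 1) evaluations", {
  d <- build_trajectories(n = 63, p = 4, t = 10, seed = 1)
  expect_equal(nrow(d$points), 640L)
  expect_error(build_trajectories(n = 3, p = 5, t = 4), "even")
  expect_error(build_trajectories(n = 3, p = 4, t = 1), "t must be")
})

test_that("elementary effects recover linear-model coefficients exactly", {
  d <- build_trajectories(n = 2, p = 4, t = 8, seed = 3)
  y <- apply(d$points, 1, function(x) 2 * x[1] + 3 * x[2])
  ee <- elementary_effects(d, y)
  expect_equal(unname(ee[, 1]), rep(2, 8), tolerance = 1e-12)
  expect_equal(unname(ee[, 2]), rep(3, 8), tolerance = 1e-12)

  y0 <- rep(5, nrow(d$points))
  expect_true(all(abs(elementary_effects(d, y0)) < 1e-12))

  expect_error(elementary_effects(d, y[-1]), "length")
  expect_error(elementary_effects(d, replace(y, 1, NA)), "non-finite")
})

test_that("interacting factors match a brute-force replay", {
  d <- build_trajectories(n = 2, p = 4, t = 10, seed = 5)
  fn <- function(x) x[1] * x[2]
  ee <- elementary_effects(d, apply(d$points, 1, fn))
  ee_brute <- brute_force_elementary_effects(fn, d)
  expect_equal(ee, ee_brute, tolerance = 1e-12)
  # product function has sigma > 0 (interaction signature)
  s <- morris_summary(ee)
  expect_true(all(s$sigma > 0))
})

test_that("summaries compute mu, mu*, sigma and ranks correctly", {
  s <- morris_summary(matrix(c(2, 2, 2, -3, 3, 0), ncol = 2),
                      factors = c("a", "b"))
  expect_equal(s$mu_star[1], 2)
  expect_equal(s$sigma[1], 0)
  expect_equal(s$mu[2], 0)
  expect_equal(s$mu_star[2], 2)
  expect_true(all(s$mu_star >= abs(s$mu)))
  expect_error(morris_summary(matrix(1:3, nrow = 1)), ">= 2")
})

test_that("linear coefficients order the mu* ranking", {
  s <- morris_sa(function(x) sum(c(1, 2, 3) * x), n = 3, t = 6, seed = 9,
                 factors = c("x1", "x2", "x3"))
  expect_equal(s$factor[order(s$rank)], c("x3", "x2", "x1"))
  expect_true(all(s$sigma < 1e-10))           # additive: no interactions
  expect_equal(s$mu_star, c(1, 2, 3), tolerance = 1e-10)
})

test_that("the above-mean screening rule includes the top factor", {
  mk <- function(ms) data.frame(factor = paste0("f", seq_along(ms)),
                                mu_star = ms)
  expect_equal(classify_influential(mk(c(10, 1, 1, 1, 1))), "f1")
  expect_equal(classify_influential(mk(c(5, 5, 5))), character(0))
  expect_setequal(classify_influential(mk(c(5, 4, 1, 1, 1))),
                  c("f1", "f2"))
  expect_error(classify_influential(data.frame(factor = character(0),
                                              mu_star = numeric(0))), "empty")
})

test_that("mu*, sigma scale linearly with the output", {
  d <- build_trajectories(n = 3, p = 4, t = 8, seed = 12)
  fn <- function(x) x[1]^2 + x[2] * x[3]
  y <- apply(d$points, 1, fn)
  s1 <- morris_summary(elementary_effects(d, y))
  s2 <- morris_summary(elementary_effects(d, 7 * y))
  expect_equal(s2$mu_star, 7 * s1$mu_star, tolerance = 1e-12)
  expect_equal(s2$sigma, 7 * s1$sigma, tolerance = 1e-12)
  expect_equal(s2$mu, 7 * s1$mu, tolerance = 1e-12)
})

test_that("the g-function's least-damped factor screens as influential", {
  g <- test_function("g_function", coef = c(0, 1, 4.5, 9, 99, 99))
  s <- morris_sa(g$fn, n = 6, t = 20, seed = 21)
  inf <- classify_influential(s)
  expect_true("1" %in% inf)
  expect_equal(s$rank[1], 1L)
})
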