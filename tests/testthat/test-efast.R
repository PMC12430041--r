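test_that("design structure follows the frequency and size rules", {
  d <- build_fast_design(n = 4, Ns = 69, M = 4, seed = 1)
  expect_equal(nrow(d$points), 4 * 69)
  expect_equal(d$omega_max, floor((69 - 1) / 8))
  expect_true(all(d$points >= 0 & d$points <= 1))
  # factor of interest carries the highest frequency in its own block
  for (i in 1:4) {
    expect_equal(d$omega[i, i], d$omega_max)
    expect_true(all(d$omega[i, -i] < d$omega_max))
  }
  d2 <- build_fast_design(n = 4, Ns = 69, M = 4, seed = 1)
  expect_identical(d$points, d2$points)

  expect_error(build_fast_design(n = 3, Ns = 40, M = 4), "validity")
  expect_warning(build_fast_design(n = 3, Ns = 40, M = 4, strict = FALSE),
                 "validity")
  expect_error(build_fast_design(n = 3, Ns = 70, M = 0), "M must be")
})

test_that("a 21-factor block design at Ns = 70 has 1470 rows per replicate", {
  d <- build_fast_design(n = 21, Ns = 70, M = 4, seed = 1)
  expect_equal(nrow(d$points), 1470L)
  # the three-year sampling plan then totals 21 * 3 * 70 = 4410 runs
  expect_equal(3L * nrow(d$points), 4410L)
})

test_that("first-order indices of an additive model match analytic values", {
  fn <- function(x) x[1] + 2 * x[2]
  r <- efast_sa(fn, n = 2, Ns = 515, M = 4, seed = 2)
  expect_equal(r$Si, c(0.2, 0.8), tolerance = 0.02)
  expect_equal(r$STi, r$Si, tolerance = 0.02)
  expect_lte(sum(r$Si), 1.05)
})

test_that("constant output is flagged degenerate with zero indices", {
  r <- efast_sa(function(x) 3.5, n = 3, Ns = 69, seed = 1)
  expect_true(all(r$degenerate))
  expect_true(all(r$Si == 0))
  expect_true(all(r$STi == 0))
})

test_that("g-function indices match the closed form at Ns = 1027", {
  g <- test_function("g_function", coef = c(0, 1, 4.5, 9, 99, 99))
  r <- efast_sa(g$fn, n = 6, Ns = 1027, M = 4, seed = 1)
  expect_true(all(abs(r$Si - analytic_sobol_indices(g)) <= 0.05))
  expect_true(all(r$STi >= r$Si - 0.02))
})

test_that("the joint Si/STi screening rule is applied", {
  r <- data.frame(factor = c("a", "b", "c"),
                  Si = c(0.06, 0.04, 0.2),
                  STi = c(0.12, 0.30, 0.05))
  expect_equal(classify_influential_fast(r), "a")
  expect_error(classify_influential_fast(r[0, ]), "empty")
})

test_that("relabeling factors permutes results up to estimator noise", {
  # frequencies and phases are assigned by block position, so relabeled
  # problems see different phase draws: equivariance holds statistically
  fn <- function(x) x[1] + 3 * x[2] * x[3]
  r1 <- efast_sa(fn, n = 3, Ns = 515, seed = 4)
  perm <- c(3, 1, 2)
  fn_p <- function(x) fn(x[perm])
  r2 <- efast_sa(fn_p, n = 3, Ns = 515, seed = 4)
  inv <- order(perm)   # factor k of the permuted problem is factor inv[k]
  expect_lt(max(abs(r2$Si - r1$Si[inv])), 0.05)
  expect_lt(max(abs(r2$STi - r1$STi[inv])), 0.07)
  expect_equal(order(-r2$STi), order(-r1$STi[inv]))
})

test_that("EFAST and Monte-Carlo Sobol estimates agree on the g-function", {
  g <- test_function("g_function", coef = c(0, 1, 4.5, 9, 99, 99))
  r <- efast_sa(g$fn, n = 6, Ns = 1027, M = 4, seed = 1)
  mc <- mc_sobol_first_order(g, n_samples = 50000, seed = 8)
  expect_true(all(abs(r$Si - mc) <= 0.06))
})

test_that("designs round-trip through the external-simulator file format", {
  d <- build_fast_design(n = 3, Ns = 69, seed = 6)
  f <- withr::local_tempfile(fileext = ".csv")
  write_design(d, f)
  df <- utils::read.csv(f)
  expect_equal(nrow(df), nrow(d$points))
  # an external batch tool appends outputs, possibly reordered
  df$output <- rowSums(df[, c("x1", "x2", "x3")])
  df <- df[rev(seq_len(nrow(df))), ]
  utils::write.csv(df, f, row.names = FALSE)
  y <- read_design_outputs(f, n_expected = nrow(d$points))
  expect_equal(y, rowSums(d$points))
})
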