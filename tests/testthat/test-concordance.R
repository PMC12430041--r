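test_that("Savage scores sum to n and weight top ranks", {
  expect_equal(savage_scores(1L), 1)
  s3 <- savage_scores(1:3)
  expect_equal(s3, c(11 / 6, 5 / 6, 1 / 3))
  for (n in c(2, 5, 21, 40)) {
    r <- sample(n)
    ss <- savage_scores(r)
    expect_equal(sum(ss), n)
    expect_true(all(diff(ss[order(r)]) < 0))   # descending in rank
  }
  expect_error(savage_scores(c(1, 1, 3)), "permutation")
  expect_error(savage_scores(c(0, 1)), "permutation")
})

test_that("identical rankings give a concordance of exactly one", {
  for (n in c(2, 5, 21)) {
    S <- matrix(rep(rev(seq_len(n)), 4), ncol = 4)
    res <- tdcc(S)
    expect_equal(res$c_t, 1, tolerance = 1e-12)
    expect_equal(res$statistic, 4 * (n - 1), tolerance = 1e-12)
  }
})

test_that("opposite two-factor rankings give zero concordance", {
  S <- cbind(c(2, 1), c(1, 2))
  res <- tdcc(S)
  expect_equal(res$c_t, 0, tolerance = 1e-12)
  expect_error(tdcc(matrix(1, 1, 2)), "2 factors")
  expect_error(tdcc(matrix(1:2, 2, 1)), "2 repetitions")
})

test_that("strong agreement on many factors is flagged significant", {
  S <- matrix(rep(21:1, 6), ncol = 6) + matrix(rnorm(126, 0, 0.01), ncol = 6)
  res <- tdcc(S)
  expect_true(res$significant)
  expect_lt(res$p_value, 0.01)
})

test_that("concordance is invariant to consistent factor relabeling", {
  set.seed(14)
  S <- matrix(runif(15), 5, 3)
  perm <- sample(5)
  expect_equal(tdcc(S[perm, ])$c_t, tdcc(S)$c_t, tolerance = 1e-12)
})

test_that("adjacent rank swaps in one column never raise concordance", {
  base <- cbind(5:1, 5:1, 5:1)
  res0 <- tdcc(base, ranks_given = FALSE)
  prev <- res0$c_t
  col <- base[, 1]
  for (i in 1:4) {
    col[c(i, i + 1)] <- col[c(i + 1, i)]
    res <- tdcc(cbind(col, base[, 2:3]))
    expect_lte(res$c_t, prev + 1e-12)
    prev <- res$c_t
  }
})

test_that("tied measures share averaged Savage scores and keep the sum", {
  s <- c(3, 3, 1, 0.5)
  sv <- cropsens:::savage_from_measure(s)
  expect_equal(sum(sv), 4)
  expect_equal(sv[1], sv[2])
  ss <- rev(cumsum(1 / (4:1)))
  expect_equal(sv[1], mean(ss[1:2]))
})

test_that("shuffled independent rankings center on the 1/m null mean", {
  # E[C_T] = 1/m under independence (so that E[T] = n - 1, the chi-square
  # mean), far below the near-1 values of concordant rankings
  set.seed(33)
  cts <- replicate(1000, tdcc(cbind(sample(6), sample(6), sample(6)),
                              ranks_given = TRUE)$c_t)
  expect_lt(abs(mean(cts) - 1 / 3), 0.05)
  expect_lt(mean(cts), 0.5)
})

test_that("chi-square p-values match a permutation null at n=6, m=3", {
  set.seed(44)
  # null distribution of the statistic under independent rankings
  stat <- replicate(10000,
    tdcc(cbind(sample(6), sample(6), sample(6)),
         ranks_given = TRUE)$statistic)
  # compare tail probabilities at several cutoffs
  for (q in c(0.25, 0.1, 0.05)) {
    crit <- stats::qchisq(q, df = 5, lower.tail = FALSE)
    emp <- mean(stat >= crit)
    expect_lt(abs(emp - q), 0.035)
  }
})

test_that("consistency reports support both column groupings", {
  set.seed(9)
  df <- expand.grid(year = 1:2, variable = c("wagt", "yield"),
                    treatment = paste0("W", 1:3),
                    factor = paste0("f", 1:6), stringsAsFactors = FALSE)
  base_measure <- rep(6:1, each = 12)
  df$mu_star <- base_measure + rnorm(nrow(df), 0, 0.01)
  rep1 <- consistency_report(df, "mu_star", mode = "columns")
  expect_equal(nrow(rep1), 4)               # year x variable cells
  expect_true(all(rep1$tdcc > 0.9))
  expect_true(all(rep1$p < 0.05))
  rep2 <- consistency_report(df, "mu_star", mode = "consensus")
  expect_equal(nrow(rep2), 12)              # cells x treatments
  expect_true(all(rep2$tdcc > 0.9))
})
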