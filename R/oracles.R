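#' Analytic test functions for validating the sensitivity engines
#'
#' Standard benchmark functions on the unit hypercube with closed-form
#' variance-based indices: `linear` (`sum(c_i x_i)`), `product`
#' (`x_1 x_2 ... x_n`), the Sobol `g_function`
#' (`prod (|4x - 2| + a_i) / (1 + a_i)`) and `ishigami` (inputs mapped
#' internally from `[0,1]^3` to `[-pi,pi]^3` so all engines keep a single
#' hypercube convention).
#'
#' @param name One of `"linear"`, `"product"`, `"g_function"`,
#'   `"ishigami"`.
#' @param coef Coefficients: `c` for linear, `a` for the g-function,
#'   `c(A, B)` for Ishigami (defaults 7, 0.1). Ignored for `product`.
#' @param n Dimension (required for `product`; inferred from `coef`
#'   otherwise).
#' @return List of class `test_function` with elements `name`, `fn`
#'   (row-wise function), `n`, `coef`.
#' @export
test_function <- function(name = c("linear", "product", "g_function",
                                   "ishigami"),
                          coef = NULL, n = NULL) {
  name <- match.arg(name)
  if (name == "linear") {
    if (is.null(coef)) coef <- c(1, 2)
    n <- length(coef)
    fn <- function(x) sum(coef * x)
  } else if (name == "product") {
    if (is.null(n)) n <- 2
    fn <- function(x) prod(x)
  } else if (name == "g_function") {
    if (is.null(coef)) coef <- c(0, 1, 4.5, 9, 99, 99)
    n <- length(coef)
    fn <- function(x) prod((abs(4 * x - 2) + coef) / (1 + coef))
  } else {
    if (is.null(coef)) coef <- c(7, 0.1)
    n <- 3
    fn <- function(x) {
      z <- -pi + 2 * pi * x
      sin(z[1]) + coef[1] * sin(z[2])^2 + coef[2] * z[3]^4 * sin(z[1])
    }
  }
  structure(list(name = name, fn = fn, n = n, coef = coef),
            class = "test_function")
}

#' Closed-form first-order Sobol indices of a test function
#'
#' `linear`: `Si = c_i^2 / sum(c^2)` (equal marginal variances).
#' `g_function`: `Vi = (1/3) / (1 + a_i)^2`, `V = prod(1 + Vi) - 1`.
#' `ishigami`: the standard closed form in A and B.
#'
#' @param fn A [test_function()] with a closed form.
#' @return Numeric vector of first-order indices.
#' @export
analytic_sobol_indices <- function(fn) {
  if (fn$name == "linear") {
    return(fn$coef^2 / sum(fn$coef^2))
  }
  if (fn$name == "g_function") {
    vi <- (1 / 3) / (1 + fn$coef)^2
    v <- prod(1 + vi) - 1
    return(vi / v)
  }
  if (fn$name == "ishigami") {
    a <- fn$coef[1]; b <- fn$coef[2]
    v1 <- 0.5 * (1 + b * pi^4 / 5)^2
    v2 <- a^2 / 8
    v3 <- 0
    v <- v1 + v2 + b^2 * pi^8 * (1 / 18 - 1 / 50) + 0  # total incl. x1-x3 interaction
    return(c(v1, v2, v3) / v)
  }
  stop("no closed form for '", fn$name, "'")
}

#' Monte-Carlo pick-and-freeze estimator of first-order indices
#'
#' An estimator independent of the Fourier machinery, used as a
#' cross-check oracle: with paired base matrices A and B,
#' `Vi = mean(y_B * (y_{A_B^i} - y_A))` (the Saltelli 2010 form) and
#' `Si = Vi / var(y)`.
#'
#' @param fn A [test_function()] (or any list with `fn`, `n`).
#' @param n_samples Base sample size (>= 1000).
#' @param seed Integer seed.
#' @return Numeric vector of Si estimates.
#' @export
mc_sobol_first_order <- function(fn, n_samples = 10000, seed = 1L) {
  if (n_samples < 1000) stop("n_samples must be >= 1000")
  k <- fn$n
  set.seed(seed)
  A <- matrix(stats::runif(n_samples * k), n_samples, k)
  B <- matrix(stats::runif(n_samples * k), n_samples, k)
  yA <- apply(A, 1, fn$fn)
  yB <- apply(B, 1, fn$fn)
  v <- stats::var(c(yA, yB))
  if (v <= 0) return(rep(0, k))
  vapply(seq_len(k), function(i) {
    ABi <- A
    ABi[, i] <- B[, i]
    yABi <- apply(ABi, 1, fn$fn)
    mean(yB * (yABi - yA)) / v
  }, numeric(1))
}

#' Brute-force replay of elementary effects
#'
#' Recomputes every elementary effect by direct function evaluation at
#' the stored design points, independent of the bookkeeping inside
#' [elementary_effects()]: for each consecutive pair of points the moved
#' coordinate is located by diffing the rows, and the finite difference
#' is divided by the signed step actually taken.
#'
#' @param fn A function on the unit hypercube (row-wise).
#' @param design A [build_trajectories()] design.
#' @return A `t x n` matrix of elementary effects.
#' @export
brute_force_elementary_effects <- function(fn, design) {
  pts <- design$points
  y <- apply(pts, 1, fn)
  ee <- matrix(NA_real_, design$t, design$n)
  for (k in seq_len(design$t)) {
    row0 <- (k - 1) * (design$n + 1)
    for (j in seq_len(design$n)) {
      a <- pts[row0 + j, ]; b <- pts[row0 + j + 1, ]
      f <- which(abs(b - a) > 1e-12)
      stopifnot(length(f) == 1)
      ee[k, f] <- (y[row0 + j + 1] - y[row0 + j]) / (b[f] - a[f])
    }
  }
  ee
}
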