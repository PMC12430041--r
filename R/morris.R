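#' Build Morris screening trajectories
#'
#' Random one-at-a-time trajectories on a p-level grid of the unit
#' hypercube. Each of the `t` trajectories visits `n + 1` points;
#' consecutive points differ in exactly one coordinate by +/- delta with
#' `delta = p / (2 (p - 1))`, the standard choice that makes every level
#' reachable, and every factor is perturbed exactly once per trajectory.
#' The full design therefore costs `t * (n + 1)` model evaluations.
#'
#' @param n Number of factors.
#' @param p Number of grid levels; must be even (the delta convention
#'   pairs levels across the midpoint).
#' @param t Number of trajectories (repetitions), at least 2.
#' @param seed Integer seed; the design is deterministic in it.
#' @return List of class `trajectory_design`: `points` (matrix, one row
#'   per evaluation), `traj` (trajectory id per row), `order` and `signs`
#'   (t x n matrices), `delta`, `n`, `p`, `t`, `seed`.
#' @export
build_trajectories <- function(n, p = 4, t = 10, seed = 1L) {
  if (p < 2 || p %% 2 != 0) stop("p must be even and >= 2")
  if (t < 2) stop("t must be >= 2")
  delta <- p / (2 * (p - 1))
  levels0 <- (0:(p - 1)) / (p - 1)
  set.seed(seed)
  pts <- matrix(NA_real_, t * (n + 1), n)
  ord <- matrix(NA_integer_, t, n)
  sgn <- matrix(NA_integer_, t, n)
  for (k in seq_len(t)) {
    signs <- sample(c(-1L, 1L), n, replace = TRUE)
    base <- vapply(signs, function(s) {
      ok <- levels0[levels0 + s * delta >= -1e-12 &
                      levels0 + s * delta <= 1 + 1e-12]
      ok[sample.int(length(ok), 1)]
    }, numeric(1))
    perm <- sample.int(n)
    x <- base
    row0 <- (k - 1) * (n + 1)
    pts[row0 + 1, ] <- x
    for (j in seq_len(n)) {
      f <- perm[j]
      x[f] <- x[f] + signs[f] * delta
      pts[row0 + 1 + j, ] <- x
    }
    ord[k, ] <- perm
    sgn[k, ] <- signs
  }
  pts[pts < 0] <- 0
  pts[pts > 1] <- 1
  structure(list(points = pts, traj = rep(seq_len(t), each = n + 1),
                 order = ord, signs = sgn, delta = delta,
                 n = n, p = p, t = t, seed = seed),
            class = "trajectory_design")
}

#' Elementary effects from a trajectory design
#'
#' For every one-coordinate move of every trajectory, the elementary
#' effect of the moved factor is `(y_after - y_before) / (sign * delta)`,
#' in unit-hypercube coordinates (sensitivity per unit of normalized
#' range, so that factors with different physical units are comparable).
#'
#' @param design A [build_trajectories()] design.
#' @param outputs Numeric vector of model outputs, one per design row.
#' @return A `t x n` matrix of elementary effects (column per factor).
#' @export
elementary_effects <- function(design, outputs) {
  if (length(outputs) != nrow(design$points)) {
    stop("outputs length must match the number of design points")
  }
  if (any(!is.finite(outputs))) stop("non-finite model output")
  ee <- matrix(NA_real_, design$t, design$n)
  for (k in seq_len(design$t)) {
    row0 <- (k - 1) * (design$n + 1)
    for (j in seq_len(design$n)) {
      f <- design$order[k, j]
      dy <- outputs[row0 + 1 + j] - outputs[row0 + j]
      ee[k, f] <- dy / (design$signs[k, f] * design$delta)
    }
  }
  ee
}

#' Summarize elementary effects into mu, mu*, sigma and ranks
#'
#' `mu` is the signed mean effect, `mu_star` the mean absolute effect
#' (robust to sign cancellation from non-monotonicity), `sigma` the
#' sample standard deviation (interaction / nonlinearity strength).
#' Ranks order factors by decreasing `mu_star`.
#'
#' @param effects Elementary-effect matrix from [elementary_effects()].
#' @param factors Optional factor labels (default column index).
#' @return `data.frame` of class `morris_summary` with columns
#'   `factor, mu, mu_star, sigma, rank, influential`.
#' @export
morris_summary <- function(effects, factors = NULL) {
  if (nrow(effects) < 2) stop("need >= 2 effects per factor for sigma")
  if (is.null(factors)) factors <- colnames(effects)
  if (is.null(factors)) factors <- as.character(seq_len(ncol(effects)))
  mu <- colMeans(effects)
  mu_star <- colMeans(abs(effects))
  sigma <- apply(effects, 2, stats::sd)
  out <- data.frame(factor = factors, mu = mu, mu_star = mu_star,
                    sigma = sigma, row.names = NULL,
                    stringsAsFactors = FALSE)
  out$rank <- rank(-out$mu_star, ties.method = "first")
  out$influential <- out$factor %in% classify_influential(out)
  class(out) <- c("morris_summary", "data.frame")
  out
}

#' Influential factors under the mu* screening rule
#'
#' A factor is influential when its `mu_star` exceeds the across-factor
#' mean of `mu_star`. The factor attaining the maximum is always
#' included: an upper cut at the maximum would exclude the single most
#' influential factor, contradicting the rule's purpose.
#'
#' @param summary A [morris_summary()] (or any data frame with `factor`
#'   and `mu_star` columns).
#' @return Character vector of influential factor labels.
#' @export
classify_influential <- function(summary) {
  if (nrow(summary) == 0) stop("empty summary")
  summary$factor[summary$mu_star > mean(summary$mu_star)]
}

#' Morris screening of a function over the unit hypercube
#'
#' Convenience wrapper: build a design, evaluate `fn` row-wise, summarize.
#'
#' @param fn Function taking a numeric vector in `[0,1]^n` (or a matrix
#'   if `vectorized`).
#' @param n,p,t,seed Design parameters, see [build_trajectories()].
#' @param factors Optional labels.
#' @param vectorized If `TRUE`, `fn` accepts the whole point matrix.
#' @return A [morris_summary()].
#' @export
morris_sa <- function(fn, n, p = 4, t = 10, seed = 1L, factors = NULL,
                      vectorized = FALSE) {
  design <- build_trajectories(n, p, t, seed)
  y <- if (vectorized) fn(design$points)
       else apply(design$points, 1, fn)
  morris_summary(elementary_effects(design, y), factors = factors)
}

#' Write a Morris summary as delimited text
#' @param summary A [morris_summary()].
#' @param path Output path.
#' @export
write_morris <- function(summary, path) {
  utils::write.csv(as.data.frame(summary), path, row.names = FALSE)
  invisible(path)
}
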