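#' Savage scores of a ranking
#'
#' The Savage score of rank `r` among `n` items is
#' `ss(r) = sum(1 / i) for i = r .. n`: it up-weights top ranks, which is
#' what makes the top-down concordance coefficient sensitive to agreement
#' among the most influential parameters and forgiving of noise in the
#' tail. Scores always sum exactly to `n`.
#'
#' @param ranks Integer vector, a permutation of `1..n` (rank 1 = most
#'   influential).
#' @return Numeric vector of Savage scores aligned with `ranks`.
#' @export
savage_scores <- function(ranks) {
  n <- length(ranks)
  if (n < 1 || !setequal(ranks, seq_len(n))) {
    stop("ranks must be a permutation of 1..n")
  }
  ss <- rev(cumsum(1 / (n:1)))  # ss[r] = sum_{i=r}^n 1/i
  ss[ranks]
}

# Savage scores from a raw sensitivity measure (largest value -> rank 1);
# tied values share the mean of the Savage scores their ranks span, which
# preserves sum(scores) == n.
savage_from_measure <- function(s) {
  n <- length(s)
  ss <- rev(cumsum(1 / (n:1)))
  sv <- ss[rank(-s, ties.method = "first")]
  stats::ave(sv, factor(s), FUN = mean)
}

#' Top-down concordance coefficient of a rank matrix
#'
#' Agreement of `m` sensitivity rankings over the same `n` factors.
#' Each column of the measure matrix is converted to Savage scores (rank
#' 1 = largest measure); with `rs_i` the row sums of scores,
#' `C_T = (sum_i rs_i^2 - m^2 n) / (m^2 (n - sum_{i=1}^n 1/i))`, 1 for
#' identical rankings. Significance uses `T = m (n - 1) C_T`, upper tail
#' of a chi-squared distribution with `n - 1` degrees of freedom.
#'
#' @param S An `n x m` matrix: sensitivity measures (default) or ranks.
#' @param ranks_given If `TRUE`, columns of `S` are already ranks
#'   (1 = most influential).
#' @return List of class `tdcc_result`: `c_t`, `statistic`, `df`,
#'   `p_value`, `significant` (p < 0.05), `n`, `m`.
#' @export
tdcc <- function(S, ranks_given = FALSE) {
  S <- as.matrix(S)
  n <- nrow(S); m <- ncol(S)
  if (n < 2) stop("need at least 2 factors")
  if (m < 2) stop("need at least 2 repetitions")
  scores <- apply(S, 2, function(col) {
    if (ranks_given) savage_scores(as.integer(col))
    else savage_from_measure(col)
  })
  rs <- rowSums(scores)
  c_t <- (sum(rs^2) - m^2 * n) / (m^2 * (n - sum(1 / seq_len(n))))
  statistic <- m * (n - 1) * c_t
  p <- stats::pchisq(statistic, df = n - 1, lower.tail = FALSE)
  structure(list(c_t = c_t, statistic = statistic, df = n - 1,
                 p_value = p, significant = p < 0.05, n = n, m = m),
            class = "tdcc_result")
}

#' @export
print.tdcc_result <- function(x, ...) {
  cat(sprintf("TDCC = %.3f (T = %.2f on %d df, p = %.3g)%s\n",
              x$c_t, x$statistic, x$df, x$p_value,
              if (x$significant) " *" else ""))
  invisible(x)
}

#' Consistency table of sensitivity rankings across treatments
#'
#' Builds, for each (year, variable) cell, the factor x treatment matrix
#' of sensitivity measures and summarizes rank agreement. Two groupings
#' are available, because a per-treatment concordance can be read either
#' way: `mode = "columns"` treats the `m` treatments as the repetitions
#' of one TDCC per year x variable; `mode = "consensus"` scores each
#' treatment against the consensus ranking (mean Savage score across all
#' treatments), yielding one TDCC per treatment as in a
#' treatment-labelled consistency table.
#'
#' @param results A data frame with columns `year`, `variable`,
#'   `treatment`, `factor` and a measure column.
#' @param measure Name of the measure column (e.g. `"mu_star"` or
#'   `"STi"`).
#' @param mode `"columns"` or `"consensus"`.
#' @return Data frame with columns `year, variable, treatment, tdcc, p`
#'   (`treatment` is `"all"` in columns mode).
#' @export
consistency_report <- function(results, measure = "mu_star",
                               mode = c("columns", "consensus")) {
  mode <- match.arg(mode)
  stopifnot(all(c("year", "variable", "treatment", "factor", measure)
                %in% names(results)))
  cells <- unique(results[, c("year", "variable")])
  out <- NULL
  for (i in seq_len(nrow(cells))) {
    sub <- results[results$year == cells$year[i] &
                     results$variable == cells$variable[i], ]
    treatments <- sort(unique(sub$treatment))
    if (length(treatments) < 2) stop("need >= 2 treatments per cell")
    factors <- sort(unique(sub$factor))
    mat <- sapply(treatments, function(tr) {
      s <- sub[sub$treatment == tr, ]
      s[[measure]][match(factors, s$factor)]
    })
    if (mode == "columns") {
      res <- tdcc(mat)
      out <- rbind(out, data.frame(year = cells$year[i],
                                   variable = cells$variable[i],
                                   treatment = "all", tdcc = res$c_t,
                                   p = res$p_value))
    } else {
      sc <- apply(mat, 2, savage_from_measure)
      consensus <- rowMeans(sc)
      for (j in seq_along(treatments)) {
        res <- tdcc(cbind(mat[, j], consensus))
        out <- rbind(out, data.frame(year = cells$year[i],
                                     variable = cells$variable[i],
                                     treatment = treatments[j],
                                     tdcc = res$c_t, p = res$p_value))
      }
    }
  }
  rownames(out) <- NULL
  out
}
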