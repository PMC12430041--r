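#' Goodness-of-fit metrics between observed and predicted values
#'
#' Computes the six agreement statistics commonly used to evaluate crop
#' model calibration: squared Pearson correlation (R2), Willmott's index
#' of agreement (d), RMSE, MAE, Nash--Sutcliffe efficiency (NSE) and the
#' RMSE-to-observed-SD ratio (RSR). The population (divide-by-n) SD
#' convention is used throughout, so `RSR^2 = 1 - NSE` holds as an exact
#' internal identity.
#'
#' @param observed,predicted Numeric vectors of equal length >= 3.
#' @param bands Grade band table for [performance_grade()].
#' @return List of class `fit_metrics`: `r2, d_index, rmse, mae, nse,
#'   rsr, grade, n`.
#' @export
fit_metrics <- function(observed, predicted, bands = grade_bands()) {
  if (length(observed) != length(predicted)) stop("length mismatch")
  n <- length(observed)
  if (n < 3) stop("need at least 3 pairs")
  obar <- mean(observed)
  sse <- sum((observed - predicted)^2)
  sso <- sum((observed - obar)^2)
  if (sso <= 0) stop("zero observed variance")
  r2 <- if (stats::sd(predicted) > 0) {
    stats::cor(observed, predicted)^2
  } else {
    0  # a constant predictor explains no variance
  }
  d_index <- 1 - sse / sum((abs(predicted - obar) + abs(observed - obar))^2)
  rmse <- sqrt(sse / n)
  mae <- mean(abs(observed - predicted))
  nse <- 1 - sse / sso
  rsr <- rmse / sqrt(sso / n)
  out <- structure(list(r2 = r2, d_index = d_index, rmse = rmse,
                        mae = mae, nse = nse, rsr = rsr, n = n),
                   class = "fit_metrics")
  out$grade <- performance_grade(out$nse, out$rsr, bands)
  out
}

#' Performance grade bands
#'
#' Joint NSE/RSR bands in the style of the usual hydrologic-model
#' grading tables: a grade requires both its NSE range and its RSR
#' ceiling, and when the two statistics disagree the worse band wins.
#' The table is data, not logic: pass a modified frame to rescale the
#' bands.
#'
#' @return Data frame with columns `grade, nse_min, rsr_max`, best first.
#' @export
grade_bands <- function() {
  data.frame(grade = c("Excellent", "Good", "Satisfactory"),
             nse_min = c(0.75, 0.65, 0.50),
             rsr_max = c(0.50, 0.60, 0.70),
             stringsAsFactors = FALSE)
}

#' Grade a model fit from its NSE and RSR
#'
#' Walks the band table from best to worst and returns the first grade
#' whose NSE floor and RSR ceiling are both met; `"Unacceptable"` when
#' none is.
#'
#' @param nse,rsr The two statistics.
#' @param bands Band table, see [grade_bands()].
#' @return Grade label (character).
#' @export
performance_grade <- function(nse, rsr, bands = grade_bands()) {
  for (i in seq_len(nrow(bands))) {
    if (nse > bands$nse_min[i] && rsr <= bands$rsr_max[i]) {
      return(bands$grade[i])
    }
  }
  "Unacceptable"
}

#' @export
print.fit_metrics <- function(x, ...) {
  cat(sprintf(
    "fit over %d pairs: R2 %.3f, d %.3f, RMSE %.2f, MAE %.2f, NSE %.2f, RSR %.2f -> %s\n",
    x$n, x$r2, x$d_index, x$rmse, x$mae, x$nse, x$rsr, x$grade))
  invisible(x)
}

#' Year-by-year evaluation of default versus optimized parameters
#'
#' For each year, predicts the observed records under both parameter
#' sets and tabulates the six metrics plus grade: two rows per year
#' (`Default`, `Optimized`), the shape of a standard calibration
#' evaluation table.
#'
#' @param observations Long-format observation records.
#' @param default_params,optimized_params Complete parameter sets.
#' @param context A [study_context()].
#' @param bands Grade band table.
#' @return Data frame with columns `year, parameter_set, r2, d_index,
#'   rmse, mae, nse, rsr, grade`.
#' @export
evaluation_report <- function(observations, default_params,
                              optimized_params, context,
                              bands = grade_bands()) {
  years <- sort(unique(observations$year))
  sets <- list(Default = default_params, Optimized = optimized_params)
  out <- NULL
  for (yr in years) {
    obs_y <- observations[observations$year == yr, ]
    if (nrow(obs_y) == 0) stop("missing year ", yr)
    for (nm in names(sets)) {
      pred <- run_emulator_grid(sets[[nm]], context, obs_y)
      m <- fit_metrics(obs_y$value, pred, bands)
      out <- rbind(out, data.frame(year = yr, parameter_set = nm,
                                   r2 = m$r2, d_index = m$d_index,
                                   rmse = m$rmse, mae = m$mae,
                                   nse = m$nse, rsr = m$rsr,
                                   grade = m$grade,
                                   stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  out
}
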