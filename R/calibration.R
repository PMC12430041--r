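#' Configuration for Bayesian parameter calibration
#'
#' Uniform priors on the bounds registry, Gaussian observation
#' likelihood, single-chain random-walk Metropolis in unit-hypercube
#' coordinates. By default only the eight yield-influential parameters
#' are free; all others are pinned at their bound midpoints.
#'
#' @param free Codes of free parameters.
#' @param n_iter Total chain length.
#' @param burn_frac Fraction of the chain discarded as burn-in.
#' @param proposal_scale Proposal SD per coordinate, as a fraction of the
#'   bound width (default 0.05).
#' @param sigma_o Observation SD of the Gaussian likelihood, kg ha-1.
#' @param seed Chain seed.
#' @return List of class `mcmc_config`.
#' @export
mcmc_config <- function(free = c("K", "T4", "P1", "T2", "E1", "G1",
                                 "T1", "T3"),
                        n_iter = 4000, burn_frac = 0.25,
                        proposal_scale = 0.05, sigma_o = 300, seed = 1L) {
  if (proposal_scale <= 0) stop("proposal_scale must be > 0")
  if (burn_frac < 0 || burn_frac >= 1) stop("burn_frac must be in [0, 1)")
  if (sigma_o <= 0) stop("sigma_o must be > 0")
  structure(list(free = free, n_iter = n_iter, burn_frac = burn_frac,
                 proposal_scale = proposal_scale, sigma_o = sigma_o,
                 seed = seed),
            class = "mcmc_config")
}

#' Gaussian log-likelihood of observations given parameters
#'
#' `sum_j [ -0.5 log(2 pi sigma_o^2) - (O_j - P_j(theta))^2 /
#' (2 sigma_o^2) ]` over the observation records, with `P_j` the
#' simulator prediction matched to record j's treatment, year and
#' variable.
#'
#' @param params Complete named parameter set (physical units).
#' @param observations Long-format records
#'   (`treatment, year, variable, value`).
#' @param context A [study_context()].
#' @param sigma_o Observation SD (> 0).
#' @return Log-likelihood (scalar).
#' @export
log_likelihood <- function(params, observations, context, sigma_o) {
  if (sigma_o <= 0) stop("sigma_o must be > 0")
  if (nrow(observations) == 0) stop("no observations")
  pred <- run_emulator_grid(params, context, observations)
  resid <- observations$value - pred
  sum(-0.5 * log(2 * pi * sigma_o^2) - resid^2 / (2 * sigma_o^2))
}

#' Random-walk Metropolis calibration of the free parameters
#'
#' Samples the posterior of the free parameters under uniform priors on
#' their bounds (proposals leaving the unit hypercube are rejected, which
#' is the Metropolis-correct treatment of a uniform prior) and the
#' Gaussian likelihood of [log_likelihood()]. Non-free parameters stay
#' pinned throughout.
#'
#' @param config An [mcmc_config()].
#' @param observations Observation records.
#' @param context A [study_context()].
#' @param pinned Complete parameter set providing the values of non-free
#'   codes (default: bound midpoints).
#' @param init Optional unit-cube start for the free block (default:
#'   midpoints, i.e. 0.5).
#' @return List of class `mcmc_chain`: `draws` (post-burn-in matrix in
#'   physical units), `log_post` trace, `acceptance_rate`, `summary`
#'   (mean/median/2.5%/97.5% per free parameter), `config`.
#' @export
run_mcmc <- function(config, observations, context,
                     pinned = midpoint_defaults(context$specs),
                     init = NULL) {
  specs <- context$specs
  free <- config$free
  if (!all(free %in% specs$code)) stop("free codes must be in the registry")
  idx <- match(free, specs$code)
  lo <- specs$lower[idx]; wd <- specs$upper[idx] - specs$lower[idx]
  params <- validate_params(pinned, specs, complete = TRUE)

  u <- if (is.null(init)) rep(0.5, length(free)) else init
  make_params <- function(u) {
    params[free] <- lo + u * wd
    params
  }
  set.seed(config$seed)
  lp <- log_likelihood(make_params(u), observations, context,
                       config$sigma_o)
  n_keep <- config$n_iter
  draws_u <- matrix(NA_real_, n_keep, length(free))
  lps <- numeric(n_keep)
  accept <- 0L
  best_u <- u; best_lp <- lp              # best point visited, start included
  for (it in seq_len(n_keep)) {
    prop <- u + stats::rnorm(length(free), 0, config$proposal_scale)
    if (all(prop >= 0 & prop <= 1)) {        # uniform prior support
      lp_prop <- log_likelihood(make_params(prop), observations, context,
                                config$sigma_o)
      if (log(stats::runif(1)) < lp_prop - lp) {
        u <- prop; lp <- lp_prop; accept <- accept + 1L
        if (lp > best_lp) { best_u <- u; best_lp <- lp }
      }
    }
    draws_u[it, ] <- u
    lps[it] <- lp
  }
  if (accept == 0L) {
    stop("no proposals accepted; proposal scale is pathological")
  }
  burn <- floor(config$burn_frac * n_keep)
  keep <- (burn + 1):n_keep
  draws <- sweep(sweep(draws_u[keep, , drop = FALSE], 2, wd, `*`),
                 2, lo, `+`)
  colnames(draws) <- free
  summ <- data.frame(
    code = free,
    mean = colMeans(draws),
    median = apply(draws, 2, stats::median),
    q2.5 = apply(draws, 2, stats::quantile, probs = 0.025),
    q97.5 = apply(draws, 2, stats::quantile, probs = 0.975),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(draws = draws, log_post = lps[keep],
                 acceptance_rate = accept / n_keep, summary = summ,
                 best = stats::setNames(lo + best_u * wd, free),
                 best_log_post = best_lp,
                 pinned = params, config = config),
            class = "mcmc_chain")
}

#' Posterior point estimates from a chain
#'
#' The posterior mean (default), the maximum-a-posteriori draw (the
#' stored post-burn-in draw with the highest log-posterior) or the best
#' point visited anywhere in the run including the start ("best", the
#' optimizer's answer: its in-sample fit can never be worse than the
#' starting parameter set), merged with the pinned values into a
#' complete parameter set ready for evaluation.
#'
#' @param chain An [run_mcmc()] chain.
#' @param type `"mean"`, `"map"` or `"best"`.
#' @return Complete named parameter set.
#' @export
posterior_point_estimate <- function(chain, type = c("mean", "map",
                                                     "best")) {
  type <- match.arg(type)
  est <- switch(type,
                mean = colMeans(chain$draws),
                map = chain$draws[which.max(chain$log_post), ],
                best = chain$best)
  params <- chain$pinned
  params[colnames(chain$draws)] <- est
  params
}

#' Write an MCMC chain as delimited text
#' @param chain An `mcmc_chain`.
#' @param path CSV path (draw index, parameter columns, log-posterior).
#' @export
write_chain <- function(chain, path) {
  df <- data.frame(draw = seq_len(nrow(chain$draws)), chain$draws,
                   log_post = chain$log_post)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
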