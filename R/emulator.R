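#' Frozen tuning constants of the wheat emulator
#'
#' Fixed named constants of the daily loop: radiation-to-biomass scaling,
#' the effective-extinction map, partitioning fractions, senescence rates,
#' the reference-demand coefficients, grain-filling efficiency and the
#' harvest-index ceiling. They were tuned once so that, over the bundled
#' parameter bounds, the emulator's influential-parameter structure
#' matches the screening results the package is designed to reproduce
#' (see the methods vignette), and they ship frozen: a regression test
#' guards every value.
#'
#' @return Named list of constants.
#' @export
emulator_constants <- function() {
  list(
    par_frac      = 0.40,    # usable fraction of global radiation
    vigor1        = 1.20,    # stage vigor, sowing -> jointing
    vigor2        = 1.60,    # stage vigor, jointing -> grain fill
    vigor_fill    = 2.70,    # stage vigor during grain filling
    stand_exp     = 0.38,    # establishment-vigor exponent on T1/400
    spike_exp     = 0.45,    # spike-capacity exponent on T2/525
    gn_g1         = 1.00,    # grain-number response exponent on G1/25
    gn_t1         = 0.65,    # grain-number exponent on T1/400 (tillering)
    gn_t2         = 0.80,    # grain-number exponent on T2/525 (spikelets)
    gn_t3         = 1.00,    # grain-number exponent on T3/120 (grain set)
    gn_ws         = 0.35,    # floret abortion under flowering-time drought
    k_floor       = 0.50,    # effective extinction = k_floor + k_scale * K
    k_scale       = 0.36,
    leaf_frac1    = 0.50,    # leaf partition, sowing -> jointing
    leaf_frac2    = 0.12,    # leaf partition, jointing -> flowering
    stem_frac1    = 0.30,
    stem_frac2    = 0.70,
    stem_frac_lag = 0.85,    # stem partition during the flowering-fill lag
    plant_density = 500,     # plants m-2 (initial LAI = I1 * density * 1e-6)
    rgr0          = 0.004,   # juvenile LAI expansion per unit thermal time
    lai_juv_max   = 5.0,     # tillering ceiling on juvenile expansion
    sen_base      = 0.0035,  # post-flowering canopy senescence, d-1
    sen_stress    = 0.45,    # scale on S1 * (1 - wstress) senescence
    nfac_exp      = 0.15,    # exponent damping the nitrogen factor
    demand_coef   = 0.0145,  # reference demand, mm per MJ m-2 per degC
    demand_t0     = 3,       # temperature offset of the demand curve
    extract_rate  = 0.13,    # extractable fraction of bucket surplus, d-1
    wilt_frac     = 0.30,    # bucket floor as a fraction of capacity
    ws_exp1       = 1.0,     # stress-sensitivity exponent, pre-jointing
    ws_exp2       = 1.3,     # stress-sensitivity exponent, jointing-fill
    ws_exp_fill   = 0.8,     # stress-sensitivity exponent, grain fill
    lag_eff       = 0.25,    # realized fraction of lag-phase rate P2
    fill_eff      = 0.42,    # realized fraction of potential fill rate P1
    p1_exp        = 1.50,    # response exponent on P1/0.0025
    fill_tt_cap   = 650,     # thermal-time extent of effective grain filling
    fill_tt_taper = 200,     # taper width of the filling window, degC d
    grain_frac    = 0.95,    # share of daily assimilate routed to grain
    lai_shade     = 4.2,     # leaf area shading the ear layer during fill
    res_frac      = 0.60,    # lag-phase assimilate stored as stem reserve
    res_release   = 0.12,    # reserve fraction released per day of filling
    ncost_scale   = 3.0,     # stem cost per unit grain-N accumulation
    cold_t        = 10,      # below this mean temp, X1 penalizes filling
    vern_t        = 6,       # chill-day threshold temperature, degC
    vern_base     = 25,      # chill days required at V1 = 0
    vern_v1       = 5,       # extra chill days per unit V1
    vern_min      = 0.35,    # development rate floor before vernalization
    hi_cap        = 0.55     # harvest-index ceiling: yield <= 0.55 * WAGT
  )
}

#' Run the wheat emulator for one parameter set
#'
#' Deterministic daily simulation from sowing to maturity. The parameter
#' set must be complete (all 21 codes) and within bounds; a weather
#' series too short for the parameter set's phenology is an error, never
#' a silent truncation (truncation would distort sensitivity estimates
#' at extreme thermal-time draws).
#'
#' @param params Complete named parameter vector in physical units.
#' @param weather A [generate_weather()] series (or `read_weather()`).
#' @param plan A [build_treatment()] plan.
#' @param specs Bounds registry used for validation (default bundled).
#' @param constants Emulator constant block; see [emulator_constants()].
#' @return List of class `sim_output`: `wagt` and `yield` (kg ha-1) plus
#'   the day indices of jointing, flowering, grain-fill onset, maturity.
#' @export
run_emulator <- function(params, weather, plan,
                         specs = load_bounds(),
                         constants = emulator_constants()) {
  params <- validate_params(params, specs, complete = TRUE)
  res <- .sim_wheat_cpp(unname(params[parameter_codes()]),
                        weather$maxt, weather$mint, weather$rain,
                        weather$radn, unname(plan$lower_limit),
                        plan$soil$capacity_mm, constants)
  if (!res$mature) {
    stop("weather series ends before the crop reaches maturity; ",
         "provide a longer series")
  }
  structure(res[c("wagt", "yield", "day_jointing", "day_flowering",
                  "day_grain_fill", "day_maturity")],
            class = "sim_output")
}

#' Batch-run the emulator over a unit-hypercube design
#'
#' Maps each design row through [to_physical()] and runs the daily loop
#' in compiled code. When several weather series are supplied (year
#' replicates), outputs are averaged across them, the default reading of
#' a multi-year screening plan.
#'
#' @param U Matrix of unit-hypercube rows (columns in registry order).
#' @param weather_list List of weather series (one per year replicate).
#' @param plan Treatment plan.
#' @param specs Bounds registry.
#' @param constants Emulator constants.
#' @return Matrix with columns `wagt`, `yield`, one row per design row.
#' @export
run_emulator_batch <- function(U, weather_list, plan,
                               specs = load_bounds(),
                               constants = emulator_constants()) {
  if (!is.list(weather_list) || inherits(weather_list, "data.frame")) {
    weather_list <- list(weather_list)
  }
  X <- to_physical(as.matrix(U), specs)
  acc <- matrix(0, nrow(X), 2)
  for (w in weather_list) {
    out <- .sim_wheat_batch_cpp(X, w$maxt, w$mint, w$rain, w$radn,
                                unname(plan$lower_limit),
                                plan$soil$capacity_mm, constants)
    if (anyNA(out)) {
      stop("some design points did not reach maturity; ",
           "extend the weather series")
    }
    acc <- acc + out
  }
  acc <- acc / length(weather_list)
  colnames(acc) <- c("wagt", "yield")
  acc
}

#' Reference atmospheric water demand for one day
#'
#' A Hargreaves-style bulk term: nonnegative, zero at zero forcing and
#' monotone increasing in both temperature and radiation. The crop demand
#' is `E1` times this reference.
#'
#' @param maxt,mint,radn Daily maximum/minimum temperature (degC) and
#'   solar radiation (MJ m-2).
#' @param constants Emulator constant block.
#' @return Demand in mm (vectorized).
#' @export
reference_demand <- function(maxt, mint, radn,
                             constants = emulator_constants()) {
  tmean <- (maxt + mint) / 2
  constants$demand_coef * radn * pmax(0, tmean + constants$demand_t0)
}

#' Bundle the fixed inputs of a simulation study
#'
#' Precomputes one weather series per year and one plan per treatment so
#' that screening, calibration and evaluation all run against identical
#' inputs. Year `i` uses seed `weather_seed_base + i`.
#'
#' @param years Number of season replicates.
#' @param treatments Treatment codes (default all six).
#' @param weather_seed_base Integer; year i is seeded with base + i.
#' @param soil A [soil_profile()].
#' @param season_days Season length passed to [generate_weather()].
#' @param specs Bounds registry.
#' @param constants Emulator constants.
#' @return List of class `study_context`.
#' @export
study_context <- function(years = 3, treatments = paste0("W", 1:6),
                          weather_seed_base = 100L,
                          soil = soil_profile(), season_days = 340L,
                          specs = load_bounds(),
                          constants = emulator_constants()) {
  weather <- lapply(seq_len(years), function(i) {
    generate_weather(seed = weather_seed_base + i, season_days = season_days)
  })
  plans <- lapply(treatments, build_treatment, soil = soil)
  names(plans) <- treatments
  structure(list(weather = weather, plans = plans, specs = specs,
                 constants = constants),
            class = "study_context")
}

#' Evaluate the emulator over a long-format treatment/year/variable grid
#'
#' Runs one simulation per unique (treatment, year) pair of `grid` and
#' returns the requested output variable per row; this is the prediction
#' backend of observation generation, the calibration likelihood and the
#' evaluation report.
#'
#' @param params Complete named parameter set.
#' @param context A [study_context()].
#' @param grid Data frame with columns `treatment`, `year`, `variable`.
#' @return Numeric vector of predictions aligned with `grid` rows.
#' @export
run_emulator_grid <- function(params, context, grid) {
  params <- validate_params(params, context$specs, complete = TRUE)
  x <- unname(params[parameter_codes()])
  combos <- unique(grid[, c("treatment", "year")])
  key <- paste(grid$treatment, grid$year)
  vals <- numeric(nrow(grid))
  for (i in seq_len(nrow(combos))) {
    tr <- combos$treatment[i]; yr <- combos$year[i]
    w <- context$weather[[yr]]
    plan <- context$plans[[tr]]
    res <- .sim_wheat_cpp(x, w$maxt, w$mint, w$rain, w$radn,
                          unname(plan$lower_limit),
                          plan$soil$capacity_mm, context$constants)
    if (!res$mature) stop("maturity not reached for ", tr, " year ", yr)
    sel <- key == paste(tr, yr)
    vals[sel] <- ifelse(grid$variable[sel] == "wagt", res$wagt, res$yield)
  }
  vals
}

#' Declare a simulator adapter
#'
#' The adapter contract any external crop simulator must honor to be
#' driven by this package's screening and calibration pipelines:
#' `evaluate(params, weather, plan)` must be pure (deterministic in its
#' inputs) and return a list with numeric `wagt` and `yield` in kg ha-1.
#' The bundled emulator is registered through the same interface, so an
#' APSIM bridge (or any batch-capable model) can be swapped in without
#' touching the analysis code.
#'
#' @param name Adapter name.
#' @param evaluate Function `(params, weather, plan) -> list(wagt, yield)`.
#' @param outputs Declared output variable names.
#' @return List of class `simulator_adapter`.
#' @export
simulator_adapter <- function(name, evaluate,
                              outputs = c("wagt", "yield")) {
  stopifnot(is.function(evaluate))
  structure(list(name = name, evaluate = evaluate, outputs = outputs),
            class = "simulator_adapter")
}

#' @export
print.sim_output <- function(x, ...) {
  cat(sprintf("wheat emulator output: WAGT %.0f kg/ha, yield %.0f kg/ha (maturity day %d)\n",
              x$wagt, x$yield, x$day_maturity))
  invisible(x)
}
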