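#' Default climate configuration for the synthetic arid site
#'
#' A temperate continental arid climate: ~190 mm annual precipitation,
#' ~6.5 degC annual mean temperature, high sunshine. Temperatures follow a
#' sinusoidal annual cycle peaking in mid July; radiation follows a
#' clear-sky cycle peaking at the summer solstice; precipitation is sparse
#' seeded events.
#'
#' @param mean_temp Annual mean air temperature, degC.
#' @param temp_amplitude Seasonal half-amplitude of the daily-mean cycle, degC.
#' @param diurnal_range Mean Tmax - Tmin spread, degC.
#' @param annual_precip Target annual precipitation, mm.
#' @param rain_prob Daily probability of a precipitation event.
#' @param radn_mean,radn_amplitude Clear-sky radiation cycle, MJ m-2 d-1.
#' @param sowing_doy Day of year of sowing (mid September).
#' @param temp_noise_sd,radn_noise_sd Daily noise SDs.
#' @return A list of class `climate_config`.
#' @export
climate_config <- function(mean_temp = 6.5, temp_amplitude = 18,
                           diurnal_range = 12, annual_precip = 190,
                           rain_prob = 0.10, radn_mean = 15.5,
                           radn_amplitude = 10.5, sowing_doy = 258,
                           temp_noise_sd = 2, radn_noise_sd = 1.5) {
  structure(as.list(environment()), class = "climate_config")
}

#' Generate a seeded synthetic daily weather series
#'
#' Deterministic in `(seed, season_days, climate)`: the same seed always
#' reproduces the same series and no global RNG state leaks out. Columns
#' follow the usual crop-model "met" naming: `day` (1 = sowing day),
#' `maxt`, `mint` (degC), `rain` (mm), `radn` (MJ m-2 d-1).
#'
#' @param seed Integer seed for the series.
#' @param season_days Number of days from sowing; default 340 so that even
#'   the slowest-developing parameter-bound corners reach maturity.
#' @param climate A [climate_config()].
#' @return A `data.frame` of class `weather_series` with attributes
#'   `seed` and `climate`.
#' @export
generate_weather <- function(seed = 42L, season_days = 340L,
                             climate = climate_config()) {
  if (season_days < 30) stop("season_days must be >= 30")
  cl <- climate
  doy <- ((cl$sowing_doy - 1 + seq_len(season_days) - 1) %% 365) + 1
  withr_seed <- function(expr) { # local RNG, restore on exit
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
            else assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    expr
  }
  withr_seed({
    tmean <- cl$mean_temp +
      cl$temp_amplitude * cos(2 * pi * (doy - 197) / 365) +
      stats::rnorm(season_days, 0, cl$temp_noise_sd)
    half <- pmax(1, cl$diurnal_range / 2 +
                   stats::rnorm(season_days, 0, cl$diurnal_range / 8))
    radn <- pmax(0.3, cl$radn_mean +
                   cl$radn_amplitude * cos(2 * pi * (doy - 172) / 365) +
                   stats::rnorm(season_days, 0, cl$radn_noise_sd))
    wet <- stats::runif(season_days) < cl$rain_prob
    amount <- stats::rexp(season_days,
                          rate = cl$rain_prob * 365 / cl$annual_precip)
    rain <- ifelse(wet, amount, 0)
  })
  ws <- data.frame(day = seq_len(season_days),
                   maxt = tmean + half, mint = tmean - half,
                   rain = rain, radn = radn)
  attr(ws, "seed") <- seed
  attr(ws, "climate") <- cl
  class(ws) <- c("weather_series", "data.frame")
  ws
}

#' Read/write weather series as delimited text
#'
#' Columns `day,maxt,mint,rain,radn`; comma- or tab-delimited.
#'
#' @param ws A weather series.
#' @param path File path.
#' @export
write_weather <- function(ws, path) {
  utils::write.csv(as.data.frame(ws)[, c("day", "maxt", "mint", "rain", "radn")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_weather
#' @export
read_weather <- function(path) {
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.csv(path, sep = sep)
  needed <- c("day", "maxt", "mint", "rain", "radn")
  if (!all(needed %in% names(df))) {
    stop("weather file must have columns: ", paste(needed, collapse = ","))
  }
  df <- df[, needed]
  class(df) <- c("weather_series", "data.frame")
  df
}

#' Soil profile for the single-bucket water balance
#'
#' @param fc Volumetric field capacity, percent (site default 26.15).
#' @param bulk_density Bulk density, g cm-3 (site default 1.62).
#' @param depth_mm Rooting/bucket depth, mm (default 600).
#' @return List of class `soil_profile`, including `capacity_mm`, the
#'   plant-available bucket size `fc/100 * depth_mm`.
#' @export
soil_profile <- function(fc = 26.15, bulk_density = 1.62, depth_mm = 600) {
  if (fc <= 0 || fc >= 100) stop("fc must be in (0, 100)")
  if (bulk_density <= 0) stop("bulk density must be positive")
  structure(list(fc = fc, bulk_density = bulk_density, depth_mm = depth_mm,
                 capacity_mm = fc / 100 * depth_mm),
            class = "soil_profile")
}

#' Growth-phase names used by the irrigation plans
#' @return Character vector of the seven phases.
#' @export
phase_names <- function() {
  c("seedling", "wintering", "greening", "jointing", "heading",
    "grain_filling", "maturity")
}

# Lower irrigation limits (%FC) per phase for the six treatments.
treatment_limits <- function() {
  m <- rbind(W1 = c(65, 65, 65, 65, 65, 65, 65),
             W2 = c(65, 65, 65, 65, 50, 50, 65),
             W3 = c(65, 65, 65, 65, 80, 80, 65),
             W4 = c(65, 65, 80, 80, 65, 65, 65),
             W5 = c(65, 65, 50, 50, 65, 65, 65),
             W6 = c(65, 65, 50, 50, 50, 65, 65))
  colnames(m) <- phase_names()
  m
}

#' Build an irrigation treatment plan
#'
#' The six soil-moisture treatments W1--W6 set a lower soil-moisture limit
#' (as a percentage of field capacity) per growth phase; irrigation refills
#' the bucket to field capacity whenever stored moisture falls below the
#' active phase's limit. The allowable depletion `smc` is
#' `FC * (1 - limit/100)` in volumetric percent: 9.15 at a 65% limit,
#' 13.07 at 50%, 5.23 at 80% for FC = 26.15.
#'
#' @param code One of `"W1"`..`"W6"`.
#' @param soil A [soil_profile()].
#' @return List of class `treatment_plan` with `code`, `lower_limit`
#'   (named vector, %FC per phase) and `smc` (volumetric %).
#' @export
build_treatment <- function(code, soil = soil_profile()) {
  lim <- treatment_limits()
  if (!is.character(code) || length(code) != 1 || !code %in% rownames(lim)) {
    stop("unknown treatment code: ", paste(code, collapse = ", "))
  }
  lower <- lim[code, ]
  structure(list(code = code, lower_limit = lower,
                 smc = soil$fc * (1 - lower / 100), soil = soil),
            class = "treatment_plan")
}

#' Synthetic observed yield/biomass records
#'
#' Runs the emulator at a known "true" parameter set for each treatment x
#' year and adds seeded Gaussian observation noise, producing records in
#' the long format `treatment,year,variable,value` used by calibration
#' and evaluation.
#'
#' @param true_params Complete named parameter set (physical units).
#' @param context A [study_context()] holding weather per year and
#'   treatment plans.
#' @param variable Which outputs to record: `"yield"`, `"wagt"`, or both.
#' @param noise_sd Observation noise SD, kg ha-1 (default 300).
#' @param seed Seed for the noise draws.
#' @return `data.frame` with columns treatment, year, variable, value.
#' @export
generate_observations <- function(true_params, context,
                                  variable = "yield", noise_sd = 300,
                                  seed = 1L) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  variable <- match.arg(variable, c("yield", "wagt"), several.ok = TRUE)
  grid <- expand.grid(treatment = names(context$plans),
                      year = seq_along(context$weather),
                      variable = variable, stringsAsFactors = FALSE)
  out <- run_emulator_grid(true_params, context, grid)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  grid$value <- out + stats::rnorm(length(out), 0, noise_sd)
  if (is.null(old)) rm(".Random.seed", envir = globalenv())
  else assign(".Random.seed", old, envir = globalenv())
  grid
}
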