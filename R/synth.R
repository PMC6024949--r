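#' Configuration for the synthetic city-panel generator
#'
#' The generator emulates the statistical structure of a national city panel:
#' by default 190 cities over 2014-2016, with cross-city annual PM2.5 means
#' calibrated so the national (cross-city) mean matches the published
#' bulletin values 62/50/47 ug/m3 and the final-year share of cities in the
#' 35-75 ug/m3 band matches ~71%. Concentrations are log-normal with a city
#' random effect (share `city_effect_share` of log-variance), so each city's
#' trajectory is positively autocorrelated across years. Income and GDP per
#' capita are log-normal and positively coupled through a Gaussian copula
#' (`income_gdp_correlation`); population is log-normal and independent.
#' Income and GDP grow at `socio_growth` per year from the first panel year.
#'
#' @param n_cities Number of cities (default 190).
#' @param years Panel years (default 2014:2016).
#' @param national_mean_by_year Target cross-city mean concentration per year,
#'   ug/m3 (default 62, 50, 47).
#' @param band_fraction_target Target fraction of cities in `band` in the
#'   final year (default 0.71).
#' @param band Concentration band, ug/m3 (default c(35, 75)).
#' @param city_effect_share Share of log-concentration variance from the
#'   persistent city effect, in `[0, 1]` (default 0.8).
#' @param income_log_mean,income_log_sd Log-scale parameters of per-capita
#'   disposable income, USD (defaults `log(3300)`, 0.45).
#' @param gdp_log_mean,gdp_log_sd Log-scale parameters of per-capita GDP, USD
#'   (defaults `log(7500)`, 0.55).
#' @param pop_log_mean,pop_log_sd Log-scale parameters of city population
#'   (defaults `log(3e6)`, 0.8).
#' @param income_gdp_correlation Gaussian-copula correlation between income
#'   and GDP (default 0.7).
#' @param socio_growth Annual growth rate of income and GDP per capita
#'   (default 0.07).
#' @param seed RNG seed (default 42).
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_cities = 190,
                             years = 2014:2016,
                             national_mean_by_year = c(62, 50, 47),
                             band_fraction_target = 0.71,
                             band = c(35, 75),
                             city_effect_share = 0.8,
                             income_log_mean = log(3300), income_log_sd = 0.45,
                             gdp_log_mean = log(7500), gdp_log_sd = 0.55,
                             pop_log_mean = log(3e6), pop_log_sd = 0.8,
                             income_gdp_correlation = 0.7,
                             socio_growth = 0.07,
                             seed = 42L) {
  stopifnot(
    n_cities >= 0, length(years) >= 1,
    length(national_mean_by_year) == length(years),
    all(national_mean_by_year > 0),
    band_fraction_target > 0, band_fraction_target < 1,
    length(band) == 2, band[1] < band[2],
    city_effect_share >= 0, city_effect_share <= 1,
    income_log_sd > 0, gdp_log_sd > 0, pop_log_sd > 0,
    income_gdp_correlation >= -1, income_gdp_correlation <= 1,
    socio_growth > -1
  )
  structure(
    list(
      n_cities = as.integer(n_cities), years = as.integer(years),
      national_mean_by_year = national_mean_by_year,
      band_fraction_target = band_fraction_target, band = band,
      city_effect_share = city_effect_share,
      income_log_mean = income_log_mean, income_log_sd = income_log_sd,
      gdp_log_mean = gdp_log_mean, gdp_log_sd = gdp_log_sd,
      pop_log_mean = pop_log_mean, pop_log_sd = pop_log_sd,
      income_gdp_correlation = income_gdp_correlation,
      socio_growth = socio_growth, seed = as.integer(seed)
    ),
    class = "generator_config"
  )
}

#' Solve log-normal parameters for a mean and band-probability target
#'
#' Finds `(meanlog, sdlog)` such that the log-normal mean equals
#' `target_mean` exactly (analytic identity `exp(meanlog + sdlog^2/2)`) and
#' the probability mass in `band` equals `target_band_prob`, by root-finding
#' on `sdlog`. For a mean inside the band the band probability decreases
#' monotonically from 1 (point mass at the mean) to 0 as dispersion grows,
#' so any target in (0, 1) is attainable; otherwise an infeasibility error
#' reports the attainable range.
#'
#' @param target_mean Target arithmetic mean (> 0).
#' @param target_band_prob Target band probability in (0, 1).
#' @param band Numeric length-2 interval, `band[1] < band[2]`.
#' @param tol Root-finding tolerance on the band probability (default 1e-9).
#' @return Named numeric vector `c(meanlog, sdlog)`.
#' @examples
#' p <- solve_lognormal_params(47, 0.71, c(35, 75))
#' exp(p[["meanlog"]] + p[["sdlog"]]^2 / 2)  # 47
#' @export
solve_lognormal_params <- function(target_mean, target_band_prob, band,
                                   tol = 1e-9) {
  stopifnot(target_mean > 0, target_band_prob > 0, target_band_prob < 1,
            length(band) == 2, band[1] < band[2], band[2] > 0)
  band_prob <- function(sdlog) {
    meanlog <- log(target_mean) - sdlog^2 / 2
    hi <- pnorm((log(band[2]) - meanlog) / sdlog)
    lo <- if (band[1] <= 0) 0 else pnorm((log(band[1]) - meanlog) / sdlog)
    hi - lo
  }
  grid <- exp(seq(log(1e-4), log(20), length.out = 400))
  vals <- vapply(grid, band_prob, numeric(1))
  f <- function(s) band_prob(s) - target_band_prob
  sign_change <- which(diff(sign(vals - target_band_prob)) != 0)
  if (length(sign_change) == 0) {
    abort(
      sprintf(
        paste0("no log-normal with mean %g attains band probability %g on [%g, %g]; ",
               "attainable range is [%.6g, %.6g]"),
        target_mean, target_band_prob, band[1], band[2], min(vals), max(vals)
      ),
      class = "aqb_calibration_error"
    )
  }
  i <- sign_change[1]
  sdlog <- uniroot(f, c(grid[i], grid[i + 1]), tol = 1e-12)$root
  if (abs(band_prob(sdlog) - target_band_prob) > max(tol, 1e-6)) {
    abort("band-probability root finding failed to converge", class = "aqb_calibration_error")
  }
  c(meanlog = log(target_mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a calibrated synthetic city panel
#'
#' Draws a panel of `n_cities` x `length(years)` records. The log-scale
#' concentration dispersion `sdlog` is solved from the final-year (mean,
#' band-probability) calibration targets and held constant across years, so
#' each year's cross-city mean equals its national target in expectation and
#' the final-year band probability equals `band_fraction_target`. City-level
#' log-concentrations share a persistent standard-normal city effect
#' (variance share `city_effect_share`), giving positive across-year
#' autocorrelation. Identical config and seed give an identical panel.
#'
#' @param cfg A [generator_config()].
#' @return A validated panel tibble (see [read_panel()]).
#' @examples
#' panel <- generate_panel(generator_config(n_cities = 10))
#' nrow(panel)  # 30
#' @export
generate_panel <- function(cfg = generator_config()) {
  stopifnot(inherits(cfg, "generator_config"))
  if (cfg$n_cities == 0) {
    return(tibble::tibble(
      city_id = character(), year = integer(), concentration = double(),
      population = double(), income = double(), gdp_per_capita = double()
    ))
  }
  final_year_mean <- cfg$national_mean_by_year[length(cfg$years)]
  pars <- solve_lognormal_params(final_year_mean, cfg$band_fraction_target, cfg$band)
  sdlog <- pars[["sdlog"]]
  meanlog_by_year <- log(cfg$national_mean_by_year) - sdlog^2 / 2

  n <- cfg$n_cities
  ny <- length(cfg$years)
  set.seed(cfg$seed)
  city_effect <- rnorm(n)
  year_noise <- matrix(rnorm(n * ny), nrow = n)
  w <- sqrt(cfg$city_effect_share)
  z <- w * city_effect + sqrt(1 - cfg$city_effect_share) * year_noise  # n x ny, N(0,1) marginals
  conc <- exp(sweep(z * sdlog, 2, meanlog_by_year, `+`))

  # income/GDP coupled via a Gaussian copula; population independent
  rho <- cfg$income_gdp_correlation
  u1 <- rnorm(n)
  u2 <- rho * u1 + sqrt(1 - rho^2) * rnorm(n)
  income0 <- exp(cfg$income_log_mean + cfg$income_log_sd * u1)
  gdp0 <- exp(cfg$gdp_log_mean + cfg$gdp_log_sd * u2)
  population <- round(exp(cfg$pop_log_mean + cfg$pop_log_sd * rnorm(n)))

  city_id <- sprintf("city_%03d", seq_len(n))
  growth <- (1 + cfg$socio_growth)^(seq_len(ny) - 1)
  panel <- tibble::tibble(
    city_id = rep(city_id, times = ny),
    year = rep(cfg$years, each = n),
    concentration = as.vector(conc),
    population = rep(population, times = ny),
    income = as.vector(outer(income0, growth)),
    gdp_per_capita = as.vector(outer(gdp0, growth))
  )
  panel <- panel[order(panel$city_id, panel$year), ]
  validate_panel(panel)
}
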