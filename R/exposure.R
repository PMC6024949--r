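#' Global assessment parameters
#'
#' Constants shared across the pipeline:
#' * `baseline_concentration` `C0` (ug/m3): concentration below which no
#'   excess burden is attributed; default 10, the WHO annual guideline.
#' * `vsl_threshold` (USD) and `income_threshold` (USD): reference value of a
#'   statistical life and the per-capita disposable income it is anchored to;
#'   defaults 248,172 and 1,939.
#' * `elasticity`: income elasticity of the VSL benefit transfer; default 0.8.
#' * `gdp_growth` (`a`) and `discount_rate` (`r`): per-capita GDP growth and
#'   social discount rate for the human-capital valuation; defaults 0.07 and
#'   0.08.
#' * `life_years_lost` (`t`): average life-years lost per premature death;
#'   default 10.
#' * `exponent_cap`: guard on `|beta * (C - C0)|`; exceeding it aborts rather
#'   than silently overflowing (catches coefficients in wrong units).
#'
#' @param baseline_concentration C0 in ug/m3 (>= 0).
#' @param vsl_threshold Reference VSL in USD (> 0).
#' @param income_threshold Reference income in USD (> 0).
#' @param elasticity Income elasticity (>= 0).
#' @param gdp_growth Annual per-capita GDP growth rate (> -1).
#' @param discount_rate Annual social discount rate (> -1).
#' @param life_years_lost Integer years (>= 0).
#' @param exponent_cap Cap on the exposure-response exponent (default 50).
#' @return An `assessment_params` list.
#' @export
assessment_params <- function(baseline_concentration = 10,
                              vsl_threshold = 248172,
                              income_threshold = 1939,
                              elasticity = 0.8,
                              gdp_growth = 0.07,
                              discount_rate = 0.08,
                              life_years_lost = 10L,
                              exponent_cap = 50) {
  stopifnot(
    baseline_concentration >= 0, vsl_threshold > 0, income_threshold > 0,
    elasticity >= 0, gdp_growth > -1, discount_rate > -1,
    life_years_lost >= 0, life_years_lost == as.integer(life_years_lost),
    exponent_cap > 0
  )
  structure(
    list(
      baseline_concentration = baseline_concentration,
      vsl_threshold = vsl_threshold, income_threshold = income_threshold,
      elasticity = elasticity, gdp_growth = gdp_growth,
      discount_rate = discount_rate,
      life_years_lost = as.integer(life_years_lost),
      exponent_cap = exponent_cap
    ),
    class = "assessment_params"
  )
}

#' Log-linear exposure-response: incidence at a concentration
#'
#' Under the Poisson relative-risk model the incidence of an endpoint at
#' annual mean concentration `C` is `E0 * exp(beta * (C - C0))`: `beta` is the
#' log-rate increase per ug/m3 above the baseline concentration `C0`, `E0`
#' the baseline incidence (annual cases per person) at `C0`.
#'
#' @param C Concentration, ug/m3 (vectorized).
#' @param C0 Baseline concentration, ug/m3.
#' @param beta Exposure-response coefficient per ug/m3.
#' @param E0 Baseline incidence, cases/person/yr (>= 0).
#' @param exponent_cap Abort if `|beta * (C - C0)|` exceeds this.
#' @return Incidence at `C`, cases/person/yr.
#' @examples
#' incidence_at(60, 10, 0.0004, 0.005)  # 0.005 * exp(0.02)
#' @export
incidence_at <- function(C, C0, beta, E0, exponent_cap = 50) {
  stopifnot(all(C >= 0), all(C0 >= 0), all(E0 >= 0))
  x <- beta * (C - C0)
  if (any(abs(x) > exponent_cap)) {
    i <- which(abs(x) > exponent_cap)[1]
    abort(
      sprintf(
        "exposure-response exponent |beta*(C-C0)| = %.3g exceeds cap %g (beta = %.3g, C = %.3g, C0 = %.3g); check coefficient units",
        abs(x[i]), exponent_cap, beta[min(i, length(beta))], C[min(i, length(C))], C0
      ),
      class = "aqb_overflow_error"
    )
  }
  E0 * exp(x)
}

#' Attributable cases for one city-year and endpoint
#'
#' Excess annual cases attributable to concentrations above baseline:
#' `HI = P * E0 * (exp(beta * (C - C0)) - 1)`. Concentrations below `C0` are
#' clamped to `C0` (zero attributable burden, `clamped = TRUE`) rather than
#' producing negative burdens: the model quantifies excess burden above the
#' guideline, not benefits below it.
#'
#' @param record One-row panel tibble (see [read_panel()]).
#' @param endpoint One-row endpoint tibble (see [load_endpoint_set()]).
#' @param params [assessment_params()].
#' @return One-row tibble: `city_id`, `year`, `endpoint`, `concentration_used`,
#'   `clamped`, `incidence_at_C`, `attributable_cases`.
#' @examples
#' rec <- tibble::tibble(city_id = "a", year = 2014L, concentration = 60,
#'                       population = 1e6, income = 3000, gdp_per_capita = 7000)
#' ep <- default_endpoint_set()[1, ]
#' attributable_cases(rec, ep, assessment_params())
#' @export
attributable_cases <- function(record, endpoint, params = assessment_params()) {
  stopifnot(nrow(record) == 1, nrow(endpoint) == 1)
  C0 <- params$baseline_concentration
  clamped <- record$concentration < C0
  C_used <- max(record$concentration, C0)
  E_C <- incidence_at(C_used, C0, endpoint$beta, endpoint$baseline_incidence,
                      exponent_cap = params$exponent_cap)
  cases <- record$population * (E_C - endpoint$baseline_incidence)
  tibble::tibble(
    city_id = record$city_id,
    year = record$year,
    endpoint = endpoint$name,
    concentration_used = C_used,
    clamped = clamped,
    incidence_at_C = E_C,
    attributable_cases = cases
  )
}

#' Attributable cases over a full panel and endpoint set
#'
#' Vectorized application of [attributable_cases()] over every (city, year,
#' endpoint) combination. Cases are kept continuous; rounding to whole cases
#' happens only in report rendering.
#'
#' @param panel Panel tibble.
#' @param endpoints Endpoint set.
#' @param params [assessment_params()].
#' @return Tibble with one row per (city, year, endpoint), columns as in
#'   [attributable_cases()].
#' @export
impact_table <- function(panel, endpoints, params = assessment_params()) {
  panel <- validate_panel(panel)
  C0 <- params$baseline_concentration
  grid <- tidyr::crossing(
    panel[c("city_id", "year", "concentration", "population")],
    tibble::tibble(
      endpoint = endpoints$name,
      beta = endpoints$beta,
      E0 = endpoints$baseline_incidence
    )
  )
  C_used <- pmax(grid$concentration, C0)
  x <- grid$beta * (C_used - C0)
  if (any(abs(x) > params$exponent_cap)) {
    incidence_at(C_used, C0, grid$beta, grid$E0, exponent_cap = params$exponent_cap)
  }
  E_C <- grid$E0 * exp(x)
  out <- tibble::tibble(
    city_id = grid$city_id,
    year = grid$year,
    endpoint = grid$endpoint,
    concentration_used = C_used,
    clamped = grid$concentration < C0,
    incidence_at_C = E_C,
    attributable_cases = grid$population * (E_C - grid$E0)
  )
  out[order(out$city_id, out$year, out$endpoint), ]
}
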