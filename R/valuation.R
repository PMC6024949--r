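#' Value of a statistical life by income benefit transfer
#'
#' Transfers a reference VSL to a city by income scaling:
#' `VSL_j = VSL_0 * (Income_j / Income_0)^elasticity`. Richer cities carry a
#' higher willingness to pay per statistical death.
#'
#' @param income Per-capita disposable income, USD (> 0, vectorized).
#' @param params [assessment_params()].
#' @return VSL in USD.
#' @examples
#' vsl(1939)           # 248172 at the reference income
#' vsl(2 * 1939)       # 248172 * 2^0.8
#' @export
vsl <- function(income, params = assessment_params()) {
  if (any(income <= 0)) abort("income must be > 0", class = "aqb_domain_error")
  params$vsl_threshold * (income / params$income_threshold)^params$elasticity
}

#' Discounted human-capital multiplier
#'
#' Sum of discounted growth factors over the lost life-years:
#' `sum_{y=1..t} ((1+a)/(1+r))^y`, computed by direct summation. Equals the
#' geometric closed form `q (1 - q^t) / (1 - q)` with `q = (1+a)/(1+r)` for
#' `q != 1`, and `t` exactly when `a == r`.
#'
#' @param a Annual per-capita GDP growth rate.
#' @param r Annual social discount rate.
#' @param t Number of life-years lost (non-negative integer).
#' @return Dimensionless multiplier.
#' @examples
#' ahc_multiplier(0.07, 0.08, 10)  # ~9.5046
#' @export
ahc_multiplier <- function(a, r, t) {
  stopifnot(t >= 0, t == as.integer(t), (1 + r) != 0)
  if (t == 0) return(0)
  q <- (1 + a) / (1 + r)
  sum(q^(seq_len(t)))
}

#' Amended human-capital value of a premature death
#'
#' Lower-bound mortality valuation: per-capita GDP of the city, projected at
#' growth `a` and discounted at rate `r` over `t` lost life-years:
#' `HCL_j = GDP_j0 * sum_{y=1..t} ((1+a)/(1+r))^y`.
#'
#' @param gdp_per_capita Per-capita GDP, USD (> 0, vectorized).
#' @param params [assessment_params()].
#' @return USD per premature death.
#' @examples
#' ahc(10000)  # ~95046
#' @export
ahc <- function(gdp_per_capita, params = assessment_params()) {
  if (any(gdp_per_capita <= 0)) abort("gdp_per_capita must be > 0", class = "aqb_domain_error")
  gdp_per_capita * ahc_multiplier(params$gdp_growth, params$discount_rate,
                                  params$life_years_lost)
}

.bounds <- c("lower_AHC", "upper_VSL")

#' Per-case cost for one city-year and endpoint under a valuation bound
#'
#' Cost semantics by `cost_rule`:
#' * `mortality_bound`: city VSL under `upper_VSL`, discounted human capital
#'   under `lower_AHC` (the two mortality bounds);
#' * `per_case_fixed`: configured cost-of-illness `unit_cost`, identical under
#'   both bounds;
#' * `vsl_fraction`: `vsl_weight` times the city VSL, identical under both
#'   bounds (chronic-disease valuation by disability weight).
#'
#' @param record One-row panel tibble.
#' @param endpoint One-row endpoint tibble.
#' @param bound `"lower_AHC"` or `"upper_VSL"`.
#' @param params [assessment_params()].
#' @return One-row tibble: `city_id`, `year`, `endpoint`, `bound`,
#'   `cost_per_case` (USD), `basis` (`vsl`, `ahc`, `coi_fixed`, `vsl_fraction`).
#' @export
unit_cost <- function(record, endpoint, bound, params = assessment_params()) {
  stopifnot(nrow(record) == 1, nrow(endpoint) == 1)
  bound <- match.arg(bound, .bounds)
  cost <- switch(endpoint$cost_rule,
    mortality_bound = if (bound == "upper_VSL") vsl(record$income, params)
                      else ahc(record$gdp_per_capita, params),
    per_case_fixed = endpoint$unit_cost,
    vsl_fraction = endpoint$vsl_weight * vsl(record$income, params),
    abort(paste0("unknown cost_rule: ", endpoint$cost_rule), class = "aqb_config_error")
  )
  basis <- switch(endpoint$cost_rule,
    mortality_bound = if (bound == "upper_VSL") "vsl" else "ahc",
    per_case_fixed = "coi_fixed",
    vsl_fraction = "vsl_fraction"
  )
  tibble::tibble(
    city_id = record$city_id, year = record$year, endpoint = endpoint$name,
    bound = bound, cost_per_case = cost, basis = basis
  )
}

#' Per-case costs over a full panel and endpoint set
#'
#' Vectorized [unit_cost()] over every (city, year, endpoint, bound).
#' Mortality endpoints carry two rows per city-year (one per bound);
#' morbidity endpoints carry a row per bound with identical cost.
#'
#' @param panel Panel tibble.
#' @param endpoints Endpoint set.
#' @param params [assessment_params()].
#' @param bounds Bounds to compute (default both).
#' @return Tibble with columns as in [unit_cost()].
#' @export
unit_cost_table <- function(panel, endpoints, params = assessment_params(),
                            bounds = .bounds) {
  panel <- validate_panel(panel)
  bounds <- match.arg(bounds, .bounds, several.ok = TRUE)
  vsl_j <- vsl(panel$income, params)
  ahc_j <- ahc(panel$gdp_per_capita, params)
  out <- tidyr::crossing(
    tibble::tibble(city_id = panel$city_id, year = panel$year,
                   .vsl = vsl_j, .ahc = ahc_j),
    tibble::tibble(endpoint = endpoints$name, cost_rule = endpoints$cost_rule,
                   .unit = endpoints$unit_cost, .w = endpoints$vsl_weight),
    tibble::tibble(bound = bounds)
  )
  upper <- out$bound == "upper_VSL"
  out$cost_per_case <- dplyr::case_when(
    out$cost_rule == "mortality_bound" & upper ~ out$.vsl,
    out$cost_rule == "mortality_bound" ~ out$.ahc,
    out$cost_rule == "per_case_fixed" ~ out$.unit,
    out$cost_rule == "vsl_fraction" ~ out$.w * out$.vsl
  )
  out$basis <- dplyr::case_when(
    out$cost_rule == "mortality_bound" & upper ~ "vsl",
    out$cost_rule == "mortality_bound" ~ "ahc",
    out$cost_rule == "per_case_fixed" ~ "coi_fixed",
    out$cost_rule == "vsl_fraction" ~ "vsl_fraction"
  )
  out[c("city_id", "year", "endpoint", "bound", "cost_per_case", "basis")]
}

#' Economic loss from attributable cases
#'
#' `EC = HI * cost_per_case`. The two inputs must describe the same (city,
#' year, endpoint) cells; a mismatch is a pairing error, not a silent join.
#'
#' @param impact Impact tibble ([impact_table()] rows).
#' @param cost Unit-cost tibble ([unit_cost_table()] rows, one bound).
#' @return Tibble: impact keys plus `bound`, `cost_per_case`, `economic_loss`
#'   (USD).
#' @export
economic_loss <- function(impact, cost) {
  key_i <- unique(paste(impact$city_id, impact$year, impact$endpoint))
  key_c <- unique(paste(cost$city_id, cost$year, cost$endpoint))
  if (!setequal(key_i, key_c)) {
    gap <- c(setdiff(key_i, key_c), setdiff(key_c, key_i))
    abort(paste0("impact/cost tables do not cover the same (city, year, endpoint) cells; ",
                 "first mismatch: ", gap[1]),
          class = "aqb_pairing_error")
  }
  merged <- dplyr::inner_join(
    impact[c("city_id", "year", "endpoint", "attributable_cases")],
    cost[c("city_id", "year", "endpoint", "bound", "cost_per_case")],
    by = c("city_id", "year", "endpoint"), relationship = "one-to-many"
  )
  merged$economic_loss <- merged$attributable_cases * merged$cost_per_case
  merged
}

#' Full loss table for a panel
#'
#' Runs exposure-response and valuation end to end: one row per (city, year,
#' endpoint, bound) with attributable cases, per-case cost and economic loss.
#'
#' @param panel Panel tibble.
#' @param endpoints Endpoint set.
#' @param params [assessment_params()].
#' @param bounds Bounds to compute (default both).
#' @return Loss tibble.
#' @export
loss_table <- function(panel, endpoints, params = assessment_params(),
                       bounds = .bounds) {
  impacts <- impact_table(panel, endpoints, params)
  costs <- unit_cost_table(panel, endpoints, params, bounds)
  economic_loss(impacts, costs)
}
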