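#' Roll losses up to city-year and national-year totals
#'
#' Aggregation follows the non-overlapping accounting rule: the mortality
#' component of the total counts only the all-cause mortality endpoint
#' (cause-specific mortalities overlap it and are reported per endpoint but
#' excluded from totals), the morbidity component sums the morbidity
#' endpoints, and `ec_total = ec_mortality + ec_morbidity` exactly. The
#' affected population is the sum of attributable cases over the five
#' `in_affected_total` endpoints.
#'
#' @param losses Loss tibble from [loss_table()] (both bounds allowed).
#' @param endpoints The endpoint set the losses were computed under.
#' @return Tibble with one row per (scope, city_id, year, bound): columns
#'   `scope` (`"city"` or `"national"`), `city_id` (`NA` for national rows),
#'   `year`, `bound`, `ec_mortality`, `ec_morbidity`, `ec_total` (USD) and
#'   `affected_population` (cases).
#' @export
rollup <- function(losses, endpoints) {
  need <- c("city_id", "year", "endpoint", "bound", "attributable_cases", "economic_loss")
  missing <- setdiff(need, names(losses))
  if (length(missing) > 0) {
    abort(paste0("loss table is missing column(s): ", paste(missing, collapse = ", ")),
          class = "aqb_schema_error")
  }
  gap <- losses |>
    dplyr::count(.data$city_id, .data$year, .data$bound) |>
    dplyr::filter(.data$n != nrow(endpoints))
  if (nrow(gap) > 0) {
    abort(
      sprintf("incomplete endpoint coverage for (%s, %s, %s): %d of %d endpoints",
              gap$city_id[1], gap$year[1], gap$bound[1], gap$n[1], nrow(endpoints)),
      class = "aqb_aggregation_error"
    )
  }
  allc <- all_cause_endpoint(endpoints)
  morb <- endpoints$name[endpoints$category == "morbidity"]
  affected <- endpoints$name[endpoints$in_affected_total]
  city <- losses |>
    dplyr::group_by(.data$city_id, .data$year, .data$bound) |>
    dplyr::summarise(
      ec_mortality = sum(.data$economic_loss[.data$endpoint %in% allc]),
      ec_morbidity = sum(.data$economic_loss[.data$endpoint %in% morb]),
      affected_population = sum(.data$attributable_cases[.data$endpoint %in% affected]),
      .groups = "drop"
    ) |>
    dplyr::mutate(ec_total = .data$ec_mortality + .data$ec_morbidity, scope = "city")
  national <- city |>
    dplyr::group_by(.data$year, .data$bound) |>
    dplyr::summarise(
      ec_mortality = sum(.data$ec_mortality),
      ec_morbidity = sum(.data$ec_morbidity),
      affected_population = sum(.data$affected_population),
      ec_total = sum(.data$ec_total),
      .groups = "drop"
    ) |>
    dplyr::mutate(scope = "national", city_id = NA_character_)
  cols <- c("scope", "city_id", "year", "bound",
            "ec_mortality", "ec_morbidity", "ec_total", "affected_population")
  dplyr::bind_rows(city, national)[cols] |>
    dplyr::arrange(.data$scope, .data$city_id, .data$year, .data$bound)
}

#' National summary statistics by year
#'
#' Per year: total economic loss under each bound, the lower/upper (AHC/VSL)
#' ratio, the mortality share of the total under each bound, and — when a
#' total-GDP series is supplied — the loss as a fraction of GDP. Ratios are
#' computed from unrounded totals; rounding belongs to report rendering.
#'
#' @param national National rows of a [rollup()] (both bounds present per year).
#' @param gdp_total Optional tibble `year`, `gdp_total` (USD).
#' @return Tibble per year: `tel_lower`, `tel_upper` (USD),
#'   `lower_upper_ratio`, `mortality_share_lower`, `mortality_share_upper`,
#'   and `tel_gdp_lower`, `tel_gdp_upper` when GDP is supplied.
#' @export
summary_stats <- function(national, gdp_total = NULL) {
  wide <- national |>
    dplyr::filter(.data$scope == "national") |>
    tidyr::pivot_wider(
      id_cols = "year", names_from = "bound",
      values_from = c("ec_total", "ec_mortality")
    )
  need <- c("ec_total_lower_AHC", "ec_total_upper_VSL")
  if (!all(need %in% names(wide))) {
    abort("summary_stats needs both bounds for every year", class = "aqb_aggregation_error")
  }
  out <- tibble::tibble(
    year = wide$year,
    tel_lower = wide$ec_total_lower_AHC,
    tel_upper = wide$ec_total_upper_VSL,
    lower_upper_ratio = wide$ec_total_lower_AHC / wide$ec_total_upper_VSL,
    mortality_share_lower = wide$ec_mortality_lower_AHC / wide$ec_total_lower_AHC,
    mortality_share_upper = wide$ec_mortality_upper_VSL / wide$ec_total_upper_VSL
  )
  if (!is.null(gdp_total)) {
    out <- dplyr::left_join(out, gdp_total[c("year", "gdp_total")], by = "year")
    if (anyNA(out$gdp_total)) warn("missing gdp_total for some years; TEL/GDP ratio omitted")
    out$tel_gdp_lower <- out$tel_lower / out$gdp_total
    out$tel_gdp_upper <- out$tel_upper / out$gdp_total
    out$gdp_total <- NULL
  }
  out
}

#' Year-over-year changes and mean annual decline
#'
#' For each consecutive year pair within a group: absolute change and percent
#' change relative to the earlier year. [mean_annual_decline()] averages the
#' year-over-year percent declines arithmetically; report rendering truncates
#' (not rounds) to one decimal, the convention under which a 14.30%/9.41%
#' two-step decline reports as 11.8%.
#'
#' @param data Tibble with a `year` column and the value column.
#' @param value Name of the value column (string).
#' @param by Optional character vector of grouping columns (e.g. `"city_id"`).
#' @return Tibble per group and consecutive year pair: `year_from`, `year_to`,
#'   `abs_change`, `pct_change` (positive = increase, percent).
#' @export
yoy_changes <- function(data, value, by = NULL) {
  stopifnot(value %in% names(data), "year" %in% names(data))
  data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::arrange(.data$year, .by_group = TRUE) |>
    dplyr::reframe(
      year_from = .data$year[-dplyr::n()],
      year_to = .data$year[-1],
      abs_change = diff(.data[[value]]),
      pct_change = 100 * diff(.data[[value]]) / .data[[value]][-dplyr::n()]
    )
}

#' @rdname yoy_changes
#' @param changes Output of [yoy_changes()] for one group.
#' @param digits Decimals kept by truncation (default 1).
#' @return Mean annual percent decline (positive = decline), truncated.
#' @examples
#' x <- tibble::tibble(year = 2014:2016, deaths = c(278444, 238622, 216164))
#' mean_annual_decline(yoy_changes(x, "deaths"))  # 11.8
#' @export
mean_annual_decline <- function(changes, digits = 1) {
  if (nrow(changes) == 0) return(NA_real_)
  trunc(mean(-changes$pct_change) * 10^digits) / 10^digits
}

#' Rank cities by total economic loss
#'
#' Cities ordered by their total economic loss summed over the requested
#' years under one bound, descending; ties broken by `city_id` lexicographic
#' order so rankings are deterministic and invariant to input row order.
#'
#' @param city_losses City rows of a [rollup()].
#' @param years Years to sum over (default: all present).
#' @param bound Valuation bound (default `"upper_VSL"`).
#' @return Tibble: `rank`, `city_id`, `ec_total` (USD over the range).
#' @export
rank_cities <- function(city_losses, years = NULL, bound = "upper_VSL") {
  bound <- match.arg(bound, .bounds)
  x <- dplyr::filter(city_losses, .data$scope == "city", .data$bound == !!bound)
  if (!is.null(years)) {
    missing_y <- setdiff(years, unique(x$year))
    if (length(missing_y) > 0) {
      abort(paste0("no city losses for year(s): ", paste(missing_y, collapse = ", ")),
            class = "aqb_aggregation_error")
    }
    x <- dplyr::filter(x, .data$year %in% !!years)
  }
  x |>
    dplyr::group_by(.data$city_id) |>
    dplyr::summarise(ec_total = sum(.data$ec_total), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$ec_total), .data$city_id) |>
    dplyr::mutate(rank = dplyr::row_number(), .before = 1)
}
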