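#' City-year exposure and socioeconomic panel I/O
#'
#' The unit of analysis is the city-year: annual mean PM2.5 concentration
#' (ug/m3), exposed population (permanent residents), per-capita disposable
#' income (USD/yr, drives the VSL benefit transfer) and per-capita GDP
#' (USD/yr, drives the human-capital valuation). `read_panel()` reads and
#' validates a CSV with header
#' `city_id,year,concentration,population,income,gdp_per_capita`;
#' `write_panel()` writes it back (round-trip identical on valid panels).
#'
#' @param path CSV path.
#' @param panel A panel tibble.
#' @return `read_panel()` returns a validated tibble, one row per (city, year).
#' @examples
#' p <- generate_panel(generator_config(n_cities = 5))
#' f <- tempfile(fileext = ".csv")
#' write_panel(p, f)
#' identical(as.data.frame(read_panel(f)), as.data.frame(p))
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) abort(paste0("panel not found: ", path), class = "aqb_io_error")
  cols <- readr::cols(
    city_id = readr::col_character(),
    year = readr::col_integer(),
    concentration = readr::col_double(),
    population = readr::col_double(),
    income = readr::col_double(),
    gdp_per_capita = readr::col_double()
  )
  raw <- suppressWarnings(readr::read_csv(path, col_types = cols, progress = FALSE))
  prob <- readr::problems(raw)
  if (nrow(prob) > 0) {
    abort(
      paste0("panel parse error at row ", prob$row[1], ", column '", prob$col[1],
             "': expected ", prob$expected[1], ", got '", prob$actual[1], "'"),
      class = "aqb_parse_error"
    )
  }
  validate_panel(raw)
}

#' @rdname read_panel
#' @export
write_panel <- function(panel, path) {
  readr::write_csv(
    panel[c("city_id", "year", "concentration", "population", "income", "gdp_per_capita")],
    path, progress = FALSE
  )
  invisible(path)
}

validate_panel <- function(panel) {
  required <- c("city_id", "year", "concentration", "population", "income", "gdp_per_capita")
  missing <- setdiff(required, names(panel))
  if (length(missing) > 0) {
    abort(paste0("panel is missing column(s): ", paste(missing, collapse = ", ")),
          class = "aqb_schema_error")
  }
  panel <- tibble::as_tibble(panel)[required]
  key <- paste(panel$city_id, panel$year)
  if (anyDuplicated(key)) {
    abort(paste0("duplicate (city_id, year): ", key[which(duplicated(key))[1]]),
          class = "aqb_validation_error")
  }
  num <- panel[c("concentration", "population", "income", "gdp_per_capita")]
  if (anyNA(panel) || !all(vapply(num, function(x) all(is.finite(x)), logical(1)))) {
    abort("panel contains missing or non-finite values", class = "aqb_validation_error")
  }
  if (any(panel$concentration < 0)) abort("concentration must be >= 0", class = "aqb_validation_error")
  if (any(panel$population < 0)) abort("population must be >= 0", class = "aqb_validation_error")
  if (any(panel$income <= 0)) abort("income must be > 0", class = "aqb_validation_error")
  if (any(panel$gdp_per_capita <= 0)) abort("gdp_per_capita must be > 0", class = "aqb_validation_error")
  panel$year <- as.integer(panel$year)
  panel
}

#' Annual mean concentration from monthly values
#'
#' Collapses monthly PM2.5 means into the annual mean per city-year, to match
#' socioeconomic data reported by calendar year. The annual value is the
#' arithmetic mean of the available monthly values; a completeness fraction
#' (`months_available / 12`) is retained for QC and city-years with fewer
#' than `min_months` months are flagged (`complete = FALSE`), following
#' common air-quality completeness practice. A city-year with zero available
#' months is an error.
#'
#' @param monthly Tibble with columns `city_id`, `year`, `month`,
#'   `concentration`; `NA` concentrations count as unavailable months.
#' @param min_months Minimum months for an unflagged annual mean (default 9).
#' @return Tibble: `city_id`, `year`, `concentration` (annual mean),
#'   `months_available`, `complete`.
#' @examples
#' m <- tibble::tibble(city_id = "a", year = 2014, month = 1:12,
#'                     concentration = seq(10, 120, by = 10))
#' annualize_concentrations(m)$concentration  # 65
#' @export
annualize_concentrations <- function(monthly, min_months = 9) {
  required <- c("city_id", "year", "month", "concentration")
  missing <- setdiff(required, names(monthly))
  if (length(missing) > 0) {
    abort(paste0("monthly table is missing column(s): ", paste(missing, collapse = ", ")),
          class = "aqb_schema_error")
  }
  if (any(stats::na.omit(monthly$concentration) < 0)) {
    abort("monthly concentrations must be >= 0", class = "aqb_validation_error")
  }
  if (any(!monthly$month %in% 1:12)) {
    abort("month must be in 1..12", class = "aqb_validation_error")
  }
  out <- monthly |>
    dplyr::group_by(.data$city_id, .data$year) |>
    dplyr::summarise(
      months_available = sum(!is.na(.data$concentration)),
      concentration = mean(.data$concentration, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::relocate("concentration", .before = "months_available") |>
    dplyr::mutate(complete = .data$months_available >= min_months)
  if (any(out$months_available == 0)) {
    bad <- out[out$months_available == 0, ]
    abort(
      paste0("no monthly values for city-year(s): ",
             paste(paste(bad$city_id, bad$year), collapse = "; ")),
      class = "aqb_missing_error"
    )
  }
  out
}
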