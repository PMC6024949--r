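#' Published national summary tables (190 Chinese cities, 2014-2016)
#'
#' National totals from a published city-level PM2.5 burden assessment of 190
#' Chinese cities over 2014-2016, shipped as plain-text reference tables.
#' `reported_health_impacts()` returns attributable cases per endpoint and
#' year plus the non-overlapping affected-population row;
#' `reported_economic_losses()` returns monetized losses per endpoint, year
#' and valuation bound (lower bound: amended human capital, AHC; upper bound:
#' value of statistical life, VSL) in hundred million USD, plus the
#' total-economic-loss row.
#'
#' These tables serve as consistency anchors: the package's rollup rules
#' (which endpoints enter the affected-population and total-loss sums) are
#' exactly the rules under which each table's summary row equals the sum of
#' its component rows.
#'
#' @return A tibble in long format: `endpoint`, `year`, and `cases`
#'   (health impacts) or `bound`, `loss_100m_usd` (economic losses).
#' @examples
#' reported_health_impacts()
#' @export
reported_health_impacts <- function() {
  raw <- readr::read_csv(
    system.file("extdata", "reported_health_impacts.csv", package = "aqburden"),
    show_col_types = FALSE, progress = FALSE
  )
  out <- tidyr::pivot_longer(raw, -"endpoint", names_to = "year", values_to = "cases")
  out$year <- as.integer(sub("^y", "", out$year))
  out
}

#' @rdname reported_health_impacts
#' @export
reported_economic_losses <- function() {
  raw <- readr::read_csv(
    system.file("extdata", "reported_economic_losses.csv", package = "aqburden"),
    show_col_types = FALSE, progress = FALSE
  )
  out <- tidyr::pivot_longer(raw, -"endpoint", names_to = "key", values_to = "loss_100m_usd")
  out$bound <- ifelse(startsWith(out$key, "ahc"), "lower_AHC", "upper_VSL")
  out$year <- as.integer(sub("^[a-z]+_", "", out$key))
  out[c("endpoint", "year", "bound", "loss_100m_usd")]
}
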