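#' Health-endpoint coefficient tables
#'
#' A health endpoint is one disease or death category whose PM2.5-attributable
#' burden is estimated: a name, a category (`mortality`/`morbidity`), a
#' duration class (`chronic`/`acute`), the exposure-response coefficient
#' `beta` (per ug/m3), the baseline incidence `baseline_incidence` (annual
#' cases per person at the baseline concentration), and a per-case cost rule:
#'
#' * `mortality_bound` — valued at the city VSL under the upper bound and the
#'   discounted human-capital value under the lower bound;
#' * `per_case_fixed` — a fixed cost-of-illness `unit_cost` in USD per case,
#'   identical under both bounds;
#' * `vsl_fraction` — `vsl_weight` times the city VSL (used for chronic
#'   bronchitis, conventionally weighted at 0.055 of the VSL), identical under
#'   both bounds.
#'
#' `in_affected_total` marks the five non-overlapping endpoints whose
#' attributable cases sum to the "affected population": all-cause mortality
#' plus the four morbidity endpoints. Cause-specific mortalities
#' (cardiovascular, respiratory, lung cancer) overlap the all-cause count and
#' are reported but excluded from affected-population and total-loss rollups.
#'
#' `load_endpoint_set()` reads and validates a CSV with header
#' `name,category,duration,beta,baseline_incidence,cost_rule,unit_cost,vsl_weight,in_affected_total`.
#' `write_endpoint_set()` writes the same schema back (round-trip identical).
#' `default_endpoint_set()` loads the packaged configuration: eight endpoints
#' (four mortality, four morbidity) with illustrative coefficient values —
#' exposure-response coefficients and baseline incidences are meta-analysis
#' inputs, not package constants, and should be replaced with study-specific
#' values for real assessments.
#'
#' @param path Path to an endpoint CSV.
#' @param set An endpoint set tibble as returned by `load_endpoint_set()`.
#' @param provenance Free-text source note attached as attribute.
#' @return A tibble of endpoints with class `endpoint_set` and a `provenance`
#'   attribute.
#' @examples
#' eps <- default_endpoint_set()
#' validate_affected_partition(eps)
#' @name endpoint_set
NULL

.endpoint_cols <- c(
  "name", "category", "duration", "beta", "baseline_incidence",
  "cost_rule", "unit_cost", "vsl_weight", "in_affected_total"
)

#' @rdname endpoint_set
#' @export
load_endpoint_set <- function(path, provenance = path) {
  if (!file.exists(path)) {
    abort(paste0("endpoint config not found: ", path), class = "aqb_io_error")
  }
  raw <- suppressWarnings(readr::read_csv(path, show_col_types = FALSE, progress = FALSE))
  missing <- setdiff(.endpoint_cols, names(raw))
  if (length(missing) > 0) {
    abort(
      paste0("endpoint config is missing column(s): ", paste(missing, collapse = ", ")),
      class = "aqb_schema_error"
    )
  }
  eps <- tibble::as_tibble(raw[.endpoint_cols])
  eps$name <- as.character(eps$name)
  eps$in_affected_total <- as.logical(eps$in_affected_total)
  validate_endpoint_set(eps, provenance = provenance)
}

#' @rdname endpoint_set
#' @export
write_endpoint_set <- function(set, path) {
  readr::write_csv(tibble::as_tibble(unclass(set))[.endpoint_cols], path, progress = FALSE)
  invisible(path)
}

#' @rdname endpoint_set
#' @export
default_endpoint_set <- function() {
  load_endpoint_set(
    system.file("extdata", "endpoints_default.csv", package = "aqburden"),
    provenance = "packaged default; beta/E0 and COI costs are illustrative placeholders"
  )
}

validate_endpoint_set <- function(eps, provenance = NULL) {
  bad_row <- function(msg, rows) {
    abort(
      paste0(msg, " (row ", paste(rows, collapse = ", "), ")"),
      class = "aqb_validation_error"
    )
  }
  if (anyDuplicated(eps$name)) {
    bad_row("duplicate endpoint name", which(duplicated(eps$name)))
  }
  if (!all(eps$category %in% c("mortality", "morbidity"))) {
    bad_row("category must be 'mortality' or 'morbidity'",
            which(!eps$category %in% c("mortality", "morbidity")))
  }
  if (!all(eps$duration %in% c("chronic", "acute"))) {
    bad_row("duration must be 'chronic' or 'acute'",
            which(!eps$duration %in% c("chronic", "acute")))
  }
  if (!all(eps$cost_rule %in% c("per_case_fixed", "vsl_fraction", "mortality_bound"))) {
    bad_row("unknown cost_rule", which(!eps$cost_rule %in%
      c("per_case_fixed", "vsl_fraction", "mortality_bound")))
  }
  if (!all(is.finite(eps$beta))) bad_row("beta must be finite", which(!is.finite(eps$beta)))
  if (any(eps$baseline_incidence < 0)) {
    bad_row("baseline_incidence must be >= 0", which(eps$baseline_incidence < 0))
  }
  if (any(eps$unit_cost < 0)) bad_row("unit_cost must be >= 0", which(eps$unit_cost < 0))
  if (any(eps$vsl_weight < 0 | eps$vsl_weight > 1)) {
    bad_row("vsl_weight must be in [0, 1]", which(eps$vsl_weight < 0 | eps$vsl_weight > 1))
  }
  if (any(eps$cost_rule == "mortality_bound" & eps$category != "mortality")) {
    bad_row("cost_rule 'mortality_bound' is only valid for mortality endpoints",
            which(eps$cost_rule == "mortality_bound" & eps$category != "mortality"))
  }
  n_allcause <- sum(eps$category == "mortality" & eps$in_affected_total)
  if (n_allcause != 1) {
    abort(
      paste0("endpoint set must contain exactly one all-cause mortality endpoint ",
             "(mortality with in_affected_total = TRUE); found ", n_allcause),
      class = "aqb_validation_error"
    )
  }
  attr(eps, "provenance") <- provenance
  class(eps) <- c("endpoint_set", class(eps))
  eps
}

#' Name of the all-cause mortality endpoint
#'
#' The all-cause endpoint is the unique mortality endpoint counted in the
#' non-overlapping affected-population partition; it is the only mortality
#' endpoint entering total-loss rollups.
#'
#' @param set An endpoint set.
#' @return A single endpoint name.
#' @export
all_cause_endpoint <- function(set) {
  set$name[set$category == "mortality" & set$in_affected_total]
}

#' Check the non-overlapping affected-population partition
#'
#' Returns `TRUE` iff exactly five endpoints are flagged `in_affected_total`
#' and they are the all-cause mortality endpoint plus all four morbidity
#' endpoints (no cause-specific mortality flagged, no morbidity unflagged).
#' On failure the misflagged endpoints are reported as a warning diagnostic
#' and `FALSE` is returned.
#'
#' @param set An endpoint set.
#' @return Logical scalar.
#' @export
validate_affected_partition <- function(set) {
  flagged <- set$name[set$in_affected_total]
  expected <- c(
    set$name[set$category == "mortality" & set$in_affected_total],
    set$name[set$category == "morbidity"]
  )
  ok <- length(flagged) == 5 &&
    sum(set$category == "mortality" & set$in_affected_total) == 1 &&
    setequal(flagged, expected)
  if (!ok) {
    mort_flagged <- set$name[set$category == "mortality" & set$in_affected_total]
    bad <- c(
      if (length(mort_flagged) != 1) mort_flagged,
      setdiff(flagged, expected),
      setdiff(set$name[set$category == "morbidity"], flagged)
    )
    warn(paste0(
      "affected-population partition violated; misflagged endpoint(s): ",
      if (length(bad) > 0) paste(sort(unique(bad)), collapse = ", ") else "(wrong count)"
    ))
  }
  ok
}
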