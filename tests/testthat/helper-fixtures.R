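# in-code fixtures shared across test files

tiny_panel <- function() {
  tibble::tibble(
    city_id = rep(c("alpha", "beta"), each = 3),
    year = rep(2014:2016, 2),
    concentration = c(70, 55, 50, 45, 40, 38),
    population = c(rep(2e6, 3), rep(5e5, 3)),
    income = c(rep(3878, 3), rep(1939, 3)),
    gdp_per_capita = c(rep(10000, 3), rep(5000, 3))
  )
}

# minimal valid endpoint CSV: one all-cause mortality + one of each cost rule
tiny_endpoint_csv <- function(path = tempfile(fileext = ".csv")) {
  writeLines(c(
    "name,category,duration,beta,baseline_incidence,cost_rule,unit_cost,vsl_weight,in_affected_total",
    "all_cause_mortality,mortality,chronic,0.0004,0.005,mortality_bound,0,0,TRUE",
    "lung_cancer_mortality,mortality,chronic,0.0005,0.0005,mortality_bound,0,0,FALSE",
    "chronic_bronchitis,morbidity,chronic,0.0045,0.001,vsl_fraction,0,0.055,TRUE",
    "asthma_attack,morbidity,acute,0.002,0.05,per_case_fixed,34.2,0,TRUE"
  ), path)
  path
}

tiny_endpoints <- function() load_endpoint_set(tiny_endpoint_csv())

write_panel_csv <- function(panel, path = tempfile(fileext = ".csv")) {
  write_panel(panel, path)
  path
}

# scalar-loop oracle for the impact table: one attributable_cases() call per cell
impact_loop_oracle <- function(panel, endpoints, params = assessment_params()) {
  rows <- list()
  for (i in seq_len(nrow(panel))) {
    for (j in seq_len(nrow(endpoints))) {
      rows[[length(rows) + 1]] <- attributable_cases(panel[i, ], endpoints[j, ], params)
    }
  }
  out <- dplyr::bind_rows(rows)
  out[order(out$city_id, out$year, out$endpoint), ]
}
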