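#' Run configuration
#'
#' Assembles and validates the configuration for a full assessment run.
#' Either `panel_path` (a CSV readable by [read_panel()]) or `generator`
#' (a [generator_config()], in which case the panel is synthesised) must be
#' given. `read_run_config()` loads the same structure from a YAML file whose
#' keys mirror the arguments; nested `params`, `generator` and `mc` maps are
#' passed to [assessment_params()], [generator_config()] and the Monte Carlo
#' settings respectively.
#'
#' @param panel_path Path to a panel CSV, or `NULL` to synthesise.
#' @param endpoint_config_path Path to an endpoint CSV, or `NULL` for the
#'   packaged default.
#' @param params [assessment_params()].
#' @param generator Optional [generator_config()] used when `panel_path` is
#'   `NULL`.
#' @param bounds Valuation bounds to compute (default both).
#' @param mc Optional list of Monte Carlo settings: `n` (draws), `dists`
#'   (defaults to [default_input_dists()]), `scope`.
#' @param out_dir Output directory for report files.
#' @param seed Integer seed governing all randomness in the run.
#' @return A `run_config` list.
#' @export
run_config <- function(panel_path = NULL,
                       endpoint_config_path = NULL,
                       params = assessment_params(),
                       generator = NULL,
                       bounds = c("lower_AHC", "upper_VSL"),
                       mc = NULL,
                       out_dir = "aqburden_reports",
                       seed = 42L) {
  if (is.null(panel_path) && is.null(generator)) generator <- generator_config(seed = seed)
  if (!is.null(panel_path) && !file.exists(panel_path)) {
    abort(paste0("panel_path does not exist: ", panel_path), class = "aqb_config_error")
  }
  if (!is.null(endpoint_config_path) && !file.exists(endpoint_config_path)) {
    abort(paste0("endpoint_config_path does not exist: ", endpoint_config_path),
          class = "aqb_config_error")
  }
  bounds <- match.arg(bounds, c("lower_AHC", "upper_VSL"), several.ok = TRUE)
  structure(
    list(panel_path = panel_path, endpoint_config_path = endpoint_config_path,
         params = params, generator = generator, bounds = bounds, mc = mc,
         out_dir = out_dir, seed = as.integer(seed)),
    class = "run_config"
  )
}

#' @rdname run_config
#' @param path Path to a YAML run configuration.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config not found: ", path), class = "aqb_config_error")
  y <- yaml::read_yaml(path)
  seed <- if (!is.null(y$seed)) as.integer(y$seed) else 42L
  gen <- if (!is.null(y$generator)) do.call(generator_config, y$generator) else NULL
  run_config(
    panel_path = y$panel_path,
    endpoint_config_path = y$endpoint_config_path,
    params = if (!is.null(y$params)) do.call(assessment_params, y$params)
             else assessment_params(),
    generator = gen,
    bounds = if (!is.null(y$bounds)) unlist(y$bounds) else c("lower_AHC", "upper_VSL"),
    mc = y$mc,
    out_dir = if (!is.null(y$out_dir)) y$out_dir else "aqburden_reports",
    seed = seed
  )
}

#' Run a full assessment and write the report files
#'
#' Orchestrates the pipeline end to end: load or synthesise the panel, load
#' the endpoint set, compute attributable cases, per-case costs, losses,
#' city/national rollups, national summary statistics (including TEL/GDP,
#' with total GDP taken as `population * gdp_per_capita` summed over cities),
#' year-over-year changes, the city ranking, and — when `cfg$mc` is set —
#' Monte Carlo uncertainty. All computation happens before any file is
#' written, so a failing stage leaves no partial output; reports land in
#' `cfg$out_dir` together with a `manifest.json` recording the seed, a
#' config hash and the package version. Identical config and seed give
#' byte-identical reports.
#'
#' Report files: `impact_table.csv`, `unit_costs.csv`, `city_losses.csv`,
#' `national_summary.csv`, `summary_stats.csv`, `yoy_changes.csv`,
#' `city_ranking.csv` (+ `uncertainty.csv`, `manifest.json`).
#'
#' @param cfg A [run_config()].
#' @return Invisibly, a list with every computed table and the output paths.
#' @export
run_assessment <- function(cfg = run_config()) {
  stopifnot(inherits(cfg, "run_config"))
  panel <- if (!is.null(cfg$panel_path)) read_panel(cfg$panel_path)
           else generate_panel(cfg$generator)
  endpoints <- if (!is.null(cfg$endpoint_config_path)) {
    load_endpoint_set(cfg$endpoint_config_path)
  } else {
    default_endpoint_set()
  }

  impacts <- impact_table(panel, endpoints, cfg$params)
  costs <- unit_cost_table(panel, endpoints, cfg$params, cfg$bounds)
  losses <- economic_loss(impacts, costs)
  rolled <- rollup(losses, endpoints)
  national <- dplyr::filter(rolled, .data$scope == "national")
  city <- dplyr::filter(rolled, .data$scope == "city")

  gdp_total <- panel |>
    dplyr::group_by(year = .data$year) |>
    dplyr::summarise(gdp_total = sum(.data$population * .data$gdp_per_capita))
  stats_tbl <- if (all(c("lower_AHC", "upper_VSL") %in% cfg$bounds)) {
    summary_stats(national, gdp_total)
  } else {
    NULL
  }
  changes <- yoy_changes(national, "ec_total", by = "bound")
  ranking <- rank_cities(city, bound = cfg$bounds[length(cfg$bounds)])

  mc_res <- NULL
  if (!is.null(cfg$mc)) {
    mc_dists <- if (!is.null(cfg$mc$dists)) cfg$mc$dists else default_input_dists()
    mc_res <- propagate(
      panel, endpoints, cfg$params, dists = mc_dists,
      n = if (!is.null(cfg$mc$n)) cfg$mc$n else 1000,
      seed = cfg$seed,
      scope = if (!is.null(cfg$mc$scope)) cfg$mc$scope else "national"
    )
    mc_res$uncertainty_pct <- uncertainty_percent(mc_res)
  }

  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  wr <- function(x, name) {
    p <- file.path(cfg$out_dir, name)
    readr::write_csv(x, p, progress = FALSE)
    p
  }
  paths$impact_table <- wr(impacts, "impact_table.csv")
  paths$unit_costs <- wr(costs, "unit_costs.csv")
  paths$city_losses <- wr(city, "city_losses.csv")
  paths$national_summary <- wr(national, "national_summary.csv")
  if (!is.null(stats_tbl)) paths$summary_stats <- wr(stats_tbl, "summary_stats.csv")
  paths$yoy_changes <- wr(changes, "yoy_changes.csv")
  paths$city_ranking <- wr(ranking, "city_ranking.csv")
  if (!is.null(mc_res)) paths$uncertainty <- wr(mc_res, "uncertainty.csv")

  manifest <- list(
    package = "aqburden",
    version = as.character(utils::packageVersion("aqburden")),
    seed = cfg$seed,
    config_hash = rlang::hash(cfg),
    n_cities = length(unique(panel$city_id)),
    years = sort(unique(panel$year)),
    bounds = cfg$bounds,
    files = unname(vapply(paths, basename, character(1)))
  )
  manifest_path <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE)
  paths$manifest <- manifest_path

  invisible(list(
    panel = panel, endpoints = endpoints, impacts = impacts, costs = costs,
    losses = losses, city = city, national = national,
    summary_stats = stats_tbl, yoy_changes = changes, ranking = ranking,
    uncertainty = mc_res, paths = paths
  ))
}
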