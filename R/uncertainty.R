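#' Input uncertainty distributions
#'
#' Describes the sampling distribution of one uncertain input quantity for
#' Monte Carlo propagation. Three quantities are recognised:
#' `concentration`, `beta` (exposure-response coefficients) and `unit_cost`
#' (per-case costs). Draws are interpreted as multiplicative perturbation
#' factors applied to every baseline value of the quantity (`mode =
#' "multiplier"`, the default) or as direct values (`mode = "value"`, useful
#' for sampling a scalar such as a single coefficient).
#'
#' Families and their parameters:
#' * `normal`: `mean`, `sd`;
#' * `lognormal`: `meanlog`, `sdlog`;
#' * `triangular`: `min`, `mode_`, `max` (inverse-CDF sampler);
#' * `point`: `value` (zero spread; collapses the Monte Carlo).
#'
#' `truncate_lower` resamples draws below the bound (e.g. 0 to keep
#' coefficients non-negative).
#'
#' @param quantity One of `"concentration"`, `"beta"`, `"unit_cost"`.
#' @param family One of `"normal"`, `"lognormal"`, `"triangular"`, `"point"`.
#' @param mean,sd Normal parameters.
#' @param meanlog,sdlog Log-normal parameters.
#' @param min,mode_,max Triangular parameters (`min <= mode_ <= max`).
#' @param value Point value.
#' @param mode Draw interpretation: `"multiplier"` or `"value"`.
#' @param truncate_lower Optional lower truncation bound.
#' @return An `input_dist` list.
#' @examples
#' input_dist("beta", "normal", mean = 1, sd = 0.25, truncate_lower = 0)
#' @export
input_dist <- function(quantity, family,
                       mean = NULL, sd = NULL,
                       meanlog = NULL, sdlog = NULL,
                       min = NULL, mode_ = NULL, max = NULL,
                       value = NULL,
                       mode = c("multiplier", "value"),
                       truncate_lower = NULL) {
  quantity <- match.arg(quantity, c("concentration", "beta", "unit_cost"))
  family <- match.arg(family, c("normal", "lognormal", "triangular", "point"))
  mode <- match.arg(mode)
  pars <- switch(family,
    normal = {
      if (is.null(mean) || is.null(sd) || sd < 0) {
        abort("normal family needs mean and sd >= 0", class = "aqb_dist_error")
      }
      list(mean = mean, sd = sd)
    },
    lognormal = {
      if (is.null(meanlog) || is.null(sdlog) || sdlog < 0) {
        abort("lognormal family needs meanlog and sdlog >= 0", class = "aqb_dist_error")
      }
      list(meanlog = meanlog, sdlog = sdlog)
    },
    triangular = {
      if (is.null(min) || is.null(mode_) || is.null(max) || !(min <= mode_ && mode_ <= max)) {
        abort("triangular family needs min <= mode_ <= max", class = "aqb_dist_error")
      }
      list(min = min, mode_ = mode_, max = max)
    },
    point = {
      if (is.null(value)) abort("point family needs value", class = "aqb_dist_error")
      list(value = value)
    }
  )
  structure(
    list(quantity = quantity, family = family, pars = pars, mode = mode,
         truncate_lower = truncate_lower),
    class = "input_dist"
  )
}

#' @rdname input_dist
#' @param conc_sdlog Log-sd of the concentration multiplier (default 0.10).
#' @param beta_rel_sd Relative sd of the beta multiplier, normal truncated at
#'   0 (default 0.25, the order of meta-analysis coefficient CIs).
#' @param cost_rel_range Half-range of the triangular cost multiplier around
#'   1 (default 0.2, i.e. min 0.8, mode 1, max 1.2).
#' @export
default_input_dists <- function(conc_sdlog = 0.10, beta_rel_sd = 0.25,
                                cost_rel_range = 0.2) {
  list(
    concentration = input_dist("concentration", "lognormal",
                               meanlog = 0, sdlog = conc_sdlog),
    beta = input_dist("beta", "normal", mean = 1, sd = beta_rel_sd,
                      truncate_lower = 0),
    unit_cost = input_dist("unit_cost", "triangular",
                           min = 1 - cost_rel_range, mode_ = 1,
                           max = 1 + cost_rel_range)
  )
}

# inverse-CDF triangular sampler (no pre-installed package provides one)
.rtriangular <- function(n, min, mode_, max) {
  if (min == max) return(rep(min, n))
  u <- runif(n)
  fc <- (mode_ - min) / (max - min)
  ifelse(u < fc,
         min + sqrt(u * (max - min) * (mode_ - min)),
         max - sqrt((1 - u) * (max - min) * (max - mode_)))
}

.sample_one <- function(dist, n) {
  draw <- function(m) {
    switch(dist$family,
      normal = rnorm(m, dist$pars$mean, dist$pars$sd),
      lognormal = stats::rlnorm(m, dist$pars$meanlog, dist$pars$sdlog),
      triangular = .rtriangular(m, dist$pars$min, dist$pars$mode_, dist$pars$max),
      point = rep(dist$pars$value, m)
    )
  }
  x <- draw(n)
  if (!is.null(dist$truncate_lower)) {
    for (i in 1:100) {
      bad <- x < dist$truncate_lower
      if (!any(bad)) break
      x[bad] <- draw(sum(bad))
    }
    if (any(x < dist$truncate_lower)) {
      abort("truncation resampling failed to converge", class = "aqb_dist_error")
    }
  }
  x
}

#' Sample joint input draws
#'
#' Draws `n` independent joint samples of the configured input quantities.
#' Quantities are sampled independently; truncation is applied by
#' resampling. Reproducible given `seed`.
#'
#' @param dists Named list of [input_dist()] objects (names are ignored; the
#'   `quantity` field keys the output columns).
#' @param n Number of draws (>= 1).
#' @param seed RNG seed.
#' @return Tibble with a `draw` index column and one column per quantity.
#' @export
sample_inputs <- function(dists, n, seed = 1L) {
  stopifnot(n >= 1)
  if (inherits(dists, "input_dist")) dists <- list(dists)
  stopifnot(all(vapply(dists, inherits, logical(1), "input_dist")))
  qs <- vapply(dists, `[[`, character(1), "quantity")
  if (anyDuplicated(qs)) abort("duplicate quantity in dists", class = "aqb_dist_error")
  set.seed(seed)
  out <- tibble::tibble(draw = seq_len(n))
  for (i in seq_along(dists)) out[[qs[i]]] <- .sample_one(dists[[i]], n)
  out
}

#' Monte Carlo propagation of input uncertainty
#'
#' Runs the full deterministic pipeline (exposure-response, valuation,
#' aggregation) once per draw with the concentration, beta and per-case-cost
#' inputs perturbed by their sampled multipliers, and summarises the total
#' economic loss per year and bound. The human-capital (AHC) per-case value
#' is held point-valued: its input (per-capita GDP) carries no published
#' uncertainty, so lower-bound mortality losses vary only through cases.
#'
#' Draws producing non-finite outputs (e.g. exposure-response exponent
#' beyond the overflow cap) are rejected and counted; more than 1% rejects
#' aborts.
#'
#' @param panel Panel tibble.
#' @param endpoints Endpoint set.
#' @param params [assessment_params()].
#' @param dists Named list of [input_dist()] multipliers (default
#'   [default_input_dists()]); quantities not listed are held at 1.
#' @param n Number of draws (>= 100 for CI reporting).
#' @param seed RNG seed.
#' @param scope `"national"` (default) or `"city"`.
#' @return Tibble per (scope unit, year, bound): `n_draws`, `n_rejected`,
#'   `mean`, `ci95_low`, `ci95_high` (percentile), `relative_halfwidth`
#'   `= (ci_high - ci_low) / (2 mean)`, `prob_within_5pct` (fraction of draws
#'   within +-5% of the sample mean), `seed`.
#' @export
propagate <- function(panel, endpoints, params = assessment_params(),
                      dists = default_input_dists(), n = 1000, seed = 1L,
                      scope = c("national", "city")) {
  scope <- match.arg(scope)
  stopifnot(n >= 100)
  panel <- validate_panel(panel)

  # baseline per-(city, year, endpoint) table, ordered as impact_table orders it
  base <- tidyr::crossing(
    panel[c("city_id", "year", "concentration", "population", "income", "gdp_per_capita")],
    tibble::tibble(endpoint = endpoints$name, beta = endpoints$beta,
                   E0 = endpoints$baseline_incidence,
                   cost_rule = endpoints$cost_rule,
                   unit = endpoints$unit_cost, w = endpoints$vsl_weight)
  )
  base <- base[order(base$city_id, base$year, base$endpoint), ]
  vsl_j <- vsl(base$income, params)
  ahc_j <- ahc(base$gdp_per_capita, params)
  is_mort <- base$cost_rule == "mortality_bound"
  cost_upper0 <- dplyr::case_when(
    is_mort ~ vsl_j,
    base$cost_rule == "per_case_fixed" ~ base$unit,
    base$cost_rule == "vsl_fraction" ~ base$w * vsl_j
  )
  allc <- all_cause_endpoint(endpoints)
  include <- base$endpoint %in% c(allc, endpoints$name[endpoints$category == "morbidity"])
  group <- if (scope == "national") {
    interaction(base$year[include], drop = TRUE)
  } else {
    interaction(base$city_id[include], base$year[include], drop = TRUE)
  }

  draws <- sample_inputs(dists, n, seed)
  fc <- if ("concentration" %in% names(draws)) draws$concentration else rep(1, n)
  fb <- if ("beta" %in% names(draws)) draws$beta else rep(1, n)
  fu <- if ("unit_cost" %in% names(draws)) draws$unit_cost else rep(1, n)

  C0 <- params$baseline_concentration
  ng <- nlevels(group)
  tel_upper <- matrix(NA_real_, n, ng)
  tel_lower <- matrix(NA_real_, n, ng)
  rejected <- logical(n)
  for (k in seq_len(n)) {
    C_used <- pmax(base$concentration * fc[k], C0)
    x <- base$beta * fb[k] * (C_used - C0)
    if (any(!is.finite(x)) || any(abs(x) > params$exponent_cap) || fc[k] < 0) {
      rejected[k] <- TRUE
      next
    }
    E_C <- base$E0 * exp(x)
    cases <- base$population * (E_C - base$E0)
    ec_up <- cases * (cost_upper0 * fu[k])
    ec_lo <- ifelse(is_mort, cases * ahc_j, ec_up)
    if (any(!is.finite(ec_up)) || any(!is.finite(ec_lo))) {
      rejected[k] <- TRUE
      next
    }
    tel_upper[k, ] <- rowsum(ec_up[include], group, reorder = FALSE)[, 1]
    tel_lower[k, ] <- rowsum(ec_lo[include], group, reorder = FALSE)[, 1]
  }
  if (mean(rejected) > 0.01) {
    abort(sprintf("%.1f%% of Monte Carlo draws rejected (non-finite outputs)",
                  100 * mean(rejected)),
          class = "aqb_mc_error")
  }

  keys <- if (scope == "national") {
    tibble::tibble(city_id = NA_character_, year = as.integer(levels(group)))
  } else {
    parts <- strsplit(levels(group), ".", fixed = TRUE)
    tibble::tibble(city_id = vapply(parts, `[`, "", 1),
                   year = as.integer(vapply(parts, `[`, "", 2)))
  }
  summarise_one <- function(v) {
    v <- v[!rejected]
    ci <- quantile(v, c(0.025, 0.975), names = FALSE, type = 7)
    m <- mean(v)
    tibble::tibble(
      n_draws = n, n_rejected = sum(rejected), mean = m,
      ci95_low = ci[1], ci95_high = ci[2],
      relative_halfwidth = if (m == 0) 0 else (ci[2] - ci[1]) / (2 * m),
      prob_within_5pct = mean(abs(v - m) <= 0.05 * abs(m) + (m == 0)),
      seed = as.integer(seed)
    )
  }
  res <- dplyr::bind_rows(lapply(seq_len(ng), function(g) {
    up <- summarise_one(tel_upper[, g])
    lo <- summarise_one(tel_lower[, g])
    dplyr::bind_rows(
      dplyr::mutate(lo, bound = "lower_AHC", .before = 1),
      dplyr::mutate(up, bound = "upper_VSL", .before = 1)
    ) |>
      dplyr::mutate(scope = scope, city_id = keys$city_id[g], year = keys$year[g],
                    .before = 1)
  }))
  res[order(res$city_id, res$year, res$bound), ]
}

#' Uncertainty as exceedance of the +-5% acceptable-error band
#'
#' Converts a Monte Carlo summary into the headline uncertainty percentage:
#' `100 * (1 - prob_within_5pct)`, the percentage of simulated outcomes
#' falling outside an acceptable error of +-5% around the expected value.
#' 0% means every draw is within the band (degenerate inputs); values grow
#' monotonically with each input spread.
#'
#' @param result Output of [propagate()] (any number of rows).
#' @return Numeric vector of percentages, one per row.
#' @export
uncertainty_percent <- function(result) {
  stopifnot("prob_within_5pct" %in% names(result))
  if (any(result$n_draws < 100)) {
    abort("uncertainty_percent needs n_draws >= 100", class = "aqb_mc_error")
  }
  100 * (1 - result$prob_within_5pct)
}
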