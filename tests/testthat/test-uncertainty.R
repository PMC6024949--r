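test_that("input sampling is reproducible, truncated and unbiased", {
  pt <- input_dist("unit_cost", "point", value = 1)
  d <- sample_inputs(list(pt), 50, seed = 3)
  expect_equal(d$unit_cost, rep(1, 50))

  # CLT bound oracle: sample mean of N(0.0004, 0.0001) within 3 sd / sqrt(n)
  beta_d <- input_dist("beta", "normal", mean = 0.0004, sd = 0.0001, mode = "value")
  n <- 10000
  s <- sample_inputs(list(beta_d), n, seed = 42)
  expect_lt(abs(mean(s$beta) - 0.0004), 3 * 0.0001 / sqrt(n))

  ln <- input_dist("concentration", "lognormal", meanlog = 0, sdlog = 1,
                   truncate_lower = 0)
  expect_true(all(sample_inputs(list(ln), 2000, seed = 1)$concentration > 0))

  tr <- input_dist("unit_cost", "triangular", min = 0.8, mode_ = 1, max = 1.2)
  x <- sample_inputs(list(tr), 5000, seed = 7)$unit_cost
  expect_true(all(x >= 0.8 & x <= 1.2))
  expect_lt(abs(mean(x) - 1), 0.01)  # symmetric triangular has mean at the mode

  expect_identical(sample_inputs(list(tr), 100, seed = 9),
                   sample_inputs(list(tr), 100, seed = 9))
  expect_error(input_dist("beta", "normal", mean = 1), class = "aqb_dist_error")
  expect_error(input_dist("beta", "triangular", min = 2, mode_ = 1, max = 3),
               class = "aqb_dist_error")
})

test_that("point distributions collapse the Monte Carlo onto the deterministic pipeline", {
  panel <- generate_panel(generator_config(n_cities = 8, seed = 6L))
  eps <- default_endpoint_set()
  pts <- list(
    input_dist("concentration", "point", value = 1),
    input_dist("beta", "point", value = 1),
    input_dist("unit_cost", "point", value = 1)
  )
  res <- propagate(panel, eps, dists = pts, n = 200, seed = 11)
  expect_equal(res$relative_halfwidth, rep(0, nrow(res)))
  expect_equal(res$prob_within_5pct, rep(1, nrow(res)))
  expect_equal(uncertainty_percent(res), rep(0, nrow(res)))

  rolled <- rollup(loss_table(panel, eps), eps)
  nat <- rolled[rolled$scope == "national", ]
  key <- paste(nat$year, nat$bound)
  expect_equal(res$mean[match(key, paste(res$year, res$bound))], nat$ec_total,
               tolerance = 1e-12)
})

test_that("multiplicative log-normal cost uncertainty gives the closed-form CI width", {
  panel <- generate_panel(generator_config(n_cities = 10, seed = 12L))
  eps <- default_endpoint_set()
  dists <- list(input_dist("unit_cost", "lognormal", meanlog = 0, sdlog = 0.05))
  res <- propagate(panel, eps, dists = dists, n = 20000, seed = 13)
  up <- res[res$bound == "upper_VSL", ]
  # upper-bound TEL scales by one log-normal factor; quantile oracle:
  # halfwidth ~ (exp(1.96 s) - exp(-1.96 s)) / 2 ~ 1.96 s
  expect_equal(up$relative_halfwidth, rep(1.96 * 0.05, nrow(up)), tolerance = 0.1)
  # lower bound keeps AHC mortality cost fixed, so it varies strictly less
  lo <- res[res$bound == "lower_AHC", ]
  expect_true(all(lo$relative_halfwidth < up$relative_halfwidth))
})

test_that("AHC-bound mortality losses carry no cost uncertainty", {
  panel <- generate_panel(generator_config(n_cities = 5, seed = 20L))
  mort_only <- load_endpoint_set({
    p <- tempfile(fileext = ".csv")
    writeLines(c(
      "name,category,duration,beta,baseline_incidence,cost_rule,unit_cost,vsl_weight,in_affected_total",
      "all_cause_mortality,mortality,chronic,0.0004,0.005,mortality_bound,0,0,TRUE"
    ), p)
    p
  })
  res <- propagate(panel, mort_only,
                   dists = list(input_dist("unit_cost", "lognormal",
                                           meanlog = 0, sdlog = 0.3)),
                   n = 500, seed = 5)
  lo <- res[res$bound == "lower_AHC", ]
  expect_equal(lo$relative_halfwidth, rep(0, nrow(lo)))
  expect_equal(lo$prob_within_5pct, rep(1, nrow(lo)))
  expect_true(all(res$relative_halfwidth[res$bound == "upper_VSL"] > 0))
})

test_that("seeds fix every reported statistic and nearby seeds agree within MC error", {
  panel <- generate_panel(generator_config(n_cities = 6, seed = 9L))
  eps <- default_endpoint_set()
  r1 <- propagate(panel, eps, n = 2000, seed = 17)
  r2 <- propagate(panel, eps, n = 2000, seed = 17)
  expect_identical(r1, r2)

  r3 <- propagate(panel, eps, n = 2000, seed = 18)
  # MC standard-error oracle: mean difference bounded by combined standard errors
  se <- (r1$ci95_high - r1$ci95_low) / 3.92 / sqrt(r1$n_draws)
  expect_true(all(abs(r1$mean - r3$mean) < 6 * se))
})

test_that("band-exceedance uncertainty is monotone in spread and matches the Gaussian oracle", {
  panel <- generate_panel(generator_config(n_cities = 5, seed = 15L))
  eps <- default_endpoint_set()
  upct <- vapply(c(0.01, 0.05, 0.15, 0.5), function(s) {
    res <- propagate(panel, eps,
                     dists = list(input_dist("unit_cost", "lognormal",
                                             meanlog = 0, sdlog = s)),
                     n = 4000, seed = 23)
    mean(uncertainty_percent(res[res$bound == "upper_VSL", ]))
  }, numeric(1))
  expect_true(all(diff(upct) > 0))

  # sdlog 0.5: +-5% of the mean is ~0.1 sd, so ~92% of mass sits outside the band
  expect_gt(upct[4], 85)
  expect_lt(upct[4], 97)
})
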