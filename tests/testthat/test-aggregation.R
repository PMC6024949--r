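test_that("rollup enforces the non-overlapping accounting identities", {
  eps <- default_endpoint_set()
  panel <- generate_panel(generator_config(n_cities = 12, seed = 8L))
  lt <- loss_table(panel, eps)
  rolled <- rollup(lt, eps)

  expect_equal(rolled$ec_total, rolled$ec_mortality + rolled$ec_morbidity)

  # mortality component excludes cause-specific endpoints
  city_rows <- rolled[rolled$scope == "city", ]
  allc <- lt[lt$endpoint == "all_cause_mortality", ]
  key <- paste(city_rows$city_id, city_rows$year, city_rows$bound)
  allc_key <- paste(allc$city_id, allc$year, allc$bound)
  expect_equal(city_rows$ec_mortality, allc$economic_loss[match(key, allc_key)])

  # national totals conserve the city totals
  nat <- rolled[rolled$scope == "national", ]
  for (i in seq_len(nrow(nat))) {
    cs <- city_rows[city_rows$year == nat$year[i] & city_rows$bound == nat$bound[i], ]
    expect_equal(nat$ec_total[i], sum(cs$ec_total), tolerance = 1e-9)
    expect_equal(nat$affected_population[i], sum(cs$affected_population), tolerance = 1e-9)
  }

  # affected population counts exactly the five partition endpoints
  five <- eps$name[eps$in_affected_total]
  one <- city_rows[1, ]
  manual <- sum(lt$attributable_cases[lt$city_id == one$city_id & lt$year == one$year &
                                        lt$bound == one$bound & lt$endpoint %in% five])
  expect_equal(one$affected_population, manual, tolerance = 1e-12)
})

test_that("rollup fails loudly on incomplete endpoint coverage", {
  eps <- default_endpoint_set()
  lt <- loss_table(tiny_panel(), eps)
  gappy <- lt[!(lt$city_id == "beta" & lt$year == 2015 & lt$endpoint == "asthma_attack"), ]
  expect_error(rollup(gappy, eps), "beta", class = "aqb_aggregation_error")
})

test_that("summary statistics compute bound ratios and GDP shares", {
  eps <- default_endpoint_set()
  rolled <- rollup(loss_table(tiny_panel(), eps), eps)
  nat <- rolled[rolled$scope == "national", ]
  st <- summary_stats(nat)
  expect_equal(st$lower_upper_ratio, st$tel_lower / st$tel_upper)
  expect_true(all(st$lower_upper_ratio > 0 & st$lower_upper_ratio <= 1))

  # equal bounds collapse the ratio to exactly 1
  eq <- nat
  eq$ec_total[eq$bound == "lower_AHC"] <- eq$ec_total[eq$bound == "upper_VSL"]
  eq$ec_mortality[eq$bound == "lower_AHC"] <- eq$ec_mortality[eq$bound == "upper_VSL"]
  expect_equal(summary_stats(eq)$lower_upper_ratio, rep(1, 3))

  gdp <- tibble::tibble(year = 2014:2016, gdp_total = 1e12)
  st2 <- summary_stats(nat, gdp)
  expect_equal(st2$tel_gdp_upper, st2$tel_upper / 1e12)
  expect_warning(summary_stats(nat, tibble::tibble(year = 2014, gdp_total = 1e12)),
                 "missing gdp_total")
})

test_that("year-over-year changes and truncated mean decline reproduce hand arithmetic", {
  x <- tibble::tibble(year = 2014:2016, deaths = c(278444, 238622, 216164))
  ch <- yoy_changes(x, "deaths")
  # integer-arithmetic oracle: 100*(278444-238622)/278444 and 100*(238622-216164)/238622
  expect_equal(ch$pct_change, c(-14.3016189969976, -9.41153791352013), tolerance = 1e-12)
  expect_equal(ch$abs_change, c(-39822, -22458))
  expect_equal(mean_annual_decline(ch), 11.8)  # truncation, not rounding, of 11.8565...

  const <- tibble::tibble(year = 2014:2016, v = c(5, 5, 5))
  expect_equal(yoy_changes(const, "v")$pct_change, c(0, 0))

  two <- tibble::tibble(city_id = rep(c("up", "down"), each = 2),
                        year = rep(2014:2015, 2), v = c(10, 20, 20, 10))
  ch2 <- yoy_changes(two, "v", by = "city_id")
  expect_equal(ch2$pct_change[ch2$city_id == "up"], 100)
  expect_equal(ch2$pct_change[ch2$city_id == "down"], -50)

  single <- tibble::tibble(year = 2014, v = 1)
  expect_equal(nrow(yoy_changes(single, "v")), 0)
  expect_true(is.na(mean_annual_decline(yoy_changes(single, "v"))))
})

test_that("city rankings are deterministic, dominance-respecting and order-invariant", {
  eps <- default_endpoint_set()
  base <- generate_panel(generator_config(n_cities = 9, seed = 2L))
  big <- tibble::tibble(city_id = "zzz_mega", year = 2014:2016,
                        concentration = max(base$concentration) * 1.2,
                        population = max(base$population) * 10,
                        income = max(base$income), gdp_per_capita = max(base$gdp_per_capita))
  panel <- dplyr::bind_rows(base, big)
  rolled <- rollup(loss_table(panel, eps), eps)
  rk <- rank_cities(rolled, bound = "upper_VSL")
  expect_equal(rk$city_id[1], "zzz_mega")

  # sort-by-hand oracle on summed city totals
  city <- rolled[rolled$scope == "city" & rolled$bound == "upper_VSL", ]
  totals <- tapply(city$ec_total, city$city_id, sum)
  oracle <- names(totals)[order(-totals, names(totals))]
  expect_equal(rk$city_id, oracle)

  set.seed(4)
  shuffled <- rolled[sample.int(nrow(rolled)), ]
  expect_equal(rank_cities(shuffled, bound = "upper_VSL"), rk)

  # exact ties fall back to lexicographic city order
  twin <- panel[panel$city_id == "zzz_mega", ]
  twin$city_id <- "aaa_twin"
  rolled2 <- rollup(loss_table(dplyr::bind_rows(panel, twin), eps), eps)
  rk2 <- rank_cities(rolled2, bound = "upper_VSL")
  expect_equal(rk2$city_id[1:2], c("aaa_twin", "zzz_mega"))

  expect_error(rank_cities(rolled, years = 2020), class = "aqb_aggregation_error")
})

test_that("published national tables load in long format with both bounds", {
  hi <- reported_health_impacts()
  expect_equal(nrow(hi), 9 * 3)
  expect_equal(sort(unique(hi$year)), 2014:2016)
  el <- reported_economic_losses()
  expect_equal(sort(unique(el$bound)), c("lower_AHC", "upper_VSL"))
  expect_equal(nrow(el), 9 * 6)
})
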