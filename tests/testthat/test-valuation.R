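test_that("VSL benefit transfer follows the income power law", {
  expect_equal(vsl(1939), 248172)                    # reference income
  expect_equal(vsl(5000, assessment_params(elasticity = 0)), 248172)
  expect_equal(vsl(3878), 432092.548788651, tolerance = 1e-12)  # 248172 * 2^0.8
  expect_error(vsl(0), class = "aqb_domain_error")
  expect_error(vsl(-100), class = "aqb_domain_error")

  incomes <- seq(500, 20000, length.out = 50)
  expect_true(all(diff(vsl(incomes)) > 0))  # monotone for elasticity > 0
})

test_that("human-capital multiplier matches direct summation and the closed form", {
  expect_equal(ahc_multiplier(0.05, 0.05, 10), 10)   # q = 1, every term 1
  expect_equal(ahc_multiplier(0.07, 0.08, 0), 0)     # empty sum
  expect_equal(ahc_multiplier(0.07, 0.08, 10), 9.50462823123815, tolerance = 1e-12)

  set.seed(14)
  for (i in 1:20) {
    a <- runif(1, -0.02, 0.12); r <- runif(1, 0.01, 0.12); t <- sample(1:40, 1)
    q <- (1 + a) / (1 + r)
    if (abs(q - 1) < 1e-8) next
    expect_equal(ahc_multiplier(a, r, t), q * (1 - q^t) / (1 - q), tolerance = 1e-12)
  }
})

test_that("human-capital value scales per-capita GDP by the multiplier", {
  expect_equal(ahc(10000), 95046.2823123815, tolerance = 1e-9)
  expect_equal(ahc(10000, assessment_params(life_years_lost = 0)), 0)
  expect_equal(ahc(100, assessment_params(gdp_growth = 0, discount_rate = 0,
                                          life_years_lost = 3)), 300)
  expect_error(ahc(0), class = "aqb_domain_error")
  gdps <- seq(1000, 50000, length.out = 30)
  expect_true(all(diff(ahc(gdps)) > 0))
})

test_that("unit costs follow the endpoint's cost rule under each bound", {
  eps <- tiny_endpoints()
  rec <- tibble::tibble(city_id = "a", year = 2014L, concentration = 50,
                        population = 1e6, income = 1939, gdp_per_capita = 10000)
  cb <- eps[eps$name == "chronic_bronchitis", ]
  for (b in c("lower_AHC", "upper_VSL")) {
    expect_equal(unit_cost(rec, cb, b)$cost_per_case, 13649.46)  # 0.055 * 248172
  }
  asthma <- eps[eps$name == "asthma_attack", ]
  expect_equal(unit_cost(rec, asthma, "lower_AHC")$cost_per_case, 34.2)
  expect_equal(unit_cost(rec, asthma, "upper_VSL")$cost_per_case, 34.2)

  mort <- eps[eps$name == "all_cause_mortality", ]
  expect_equal(unit_cost(rec, mort, "lower_AHC")$cost_per_case, 95046.2823123815,
               tolerance = 1e-9)
  expect_equal(unit_cost(rec, mort, "upper_VSL")$cost_per_case, 248172)
  expect_equal(unit_cost(rec, mort, "lower_AHC")$basis, "ahc")

  bad <- mort; bad$cost_rule <- "lottery"
  expect_error(unit_cost(rec, bad, "upper_VSL"), class = "aqb_config_error")
})

test_that("economic loss is cases times cost and rejects mismatched keys", {
  imp <- tibble::tibble(city_id = "a", year = 2014L, endpoint = "e",
                        attributable_cases = 100)
  cost <- tibble::tibble(city_id = "a", year = 2014L, endpoint = "e",
                         bound = "upper_VSL", cost_per_case = 50)
  expect_equal(economic_loss(imp, cost)$economic_loss, 5000)
  imp0 <- imp; imp0$attributable_cases <- 0
  expect_equal(economic_loss(imp0, cost)$economic_loss, 0)

  # product of earlier oracle outputs: 101.0067... cases x 13,649.46 USD
  imp2 <- imp; imp2$attributable_cases <- 101.006700133779
  cost2 <- cost; cost2$cost_per_case <- 13649.46
  expect_equal(economic_loss(imp2, cost2)$economic_loss, 1378686.91320801,
               tolerance = 1e-9)

  mis <- cost; mis$endpoint <- "other"
  expect_error(economic_loss(imp, mis), class = "aqb_pairing_error")
})

test_that("morbidity losses are bound-invariant and mortality bounds are ordered", {
  panel <- tiny_panel()
  eps <- default_endpoint_set()
  lt <- loss_table(panel, eps)
  morb <- eps$name[eps$category == "morbidity"]
  wide <- tidyr::pivot_wider(
    lt[lt$endpoint %in% morb, c("city_id", "year", "endpoint", "bound", "economic_loss")],
    names_from = "bound", values_from = "economic_loss"
  )
  expect_equal(wide$lower_AHC, wide$upper_VSL)

  # every tiny-panel city has vsl(income) > ahc(gdp); bound ordering must hold citywise
  params <- assessment_params()
  stopifnot(all(vsl(panel$income, params) > ahc(panel$gdp_per_capita, params)))
  mort <- lt[lt$endpoint %in% eps$name[eps$category == "mortality"], ]
  widem <- tidyr::pivot_wider(
    mort[c("city_id", "year", "endpoint", "bound", "economic_loss")],
    names_from = "bound", values_from = "economic_loss"
  )
  expect_true(all(widem$upper_VSL >= widem$lower_AHC))
})
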