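test_that("two-part and published-curve relative risks evaluate correctly", {
  rf <- risk_function("x", "peak_day", "partially", "acute",
                      threshold = 4, slope = 0.1)
  expect_equal(evaluate_rr(rf, c(0, 4, 14)), c(1, 1, 2))
  expect_error(evaluate_rr(rf, -1), "non-negative")

  curve <- data.frame(units = c(0, 10, 20), rr = c(1, 2, 4))
  pc <- risk_function("y", "mean_weekly", "partially", "chronic",
                      form = "published_curve", curve = curve)
  expect_equal(evaluate_rr(pc, c(0, 5, 15, 30)), c(1, 1.5, 3, 4))
  expect_error(risk_function("z", "mean_weekly", "partially", "chronic",
                             form = "published_curve",
                             curve = data.frame(units = c(2, 1),
                                                rr = c(1, 2))))
})

test_that("implied AAF is the excess-over-total fraction", {
  rf <- risk_function("x", "peak_day", "partially", "acute",
                      threshold = 4, slope = 0.1)
  # all below threshold: zero
  expect_equal(implied_aaf(rf, c(1, 2, 3), rep(1, 3)), 0)
  # two equal-weight persons with RR (1, 3): (0 + 2) / (1 + 3) = 0.5
  rf2 <- risk_function("x", "peak_day", "partially", "acute",
                       threshold = 4, slope = 0.2)
  expect_equal(implied_aaf(rf2, c(0, 14), c(1, 1)), 0.5)
  # enormous slope with any drinker above threshold: AAF -> 1
  rf3 <- risk_function("x", "peak_day", "partially", "acute",
                       threshold = 4, slope = 1e12)
  expect_gt(implied_aaf(rf3, c(0, 5), c(1, 1)), 0.999999)
  expect_error(implied_aaf(rf, numeric(0), numeric(0)), "positive total")
})

test_that("slope calibration to a target AAF is exact and matches a grid oracle", {
  # target 0 gives slope 0
  st <- random_state(50, 101)
  z <- fit_two_part_slope(st$consumption, st$weights, 4, 0)
  expect_equal(z$slope, 0)

  # round trip: build RR with a known slope, compute its AAF, refit
  for (seed in 1:5) {
    st <- random_state(80, seed)
    s_true <- runif(1, 0.01, 0.5)
    rf_true <- risk_function("x", "peak_day", "partially", "acute",
                             threshold = 4, slope = s_true)
    aaf <- implied_aaf(rf_true, st$consumption, st$weights)
    rf_fit <- fit_two_part_slope(st$consumption, st$weights, 4, aaf)
    expect_equal(rf_fit$slope, s_true, tolerance = 1e-6)
    expect_equal(implied_aaf(rf_fit, st$consumption, st$weights), aaf,
                 tolerance = 1e-8)
  }

  # brute-force 10,000-point grid search oracle
  st <- random_state(60, 7)
  rf_fit <- fit_two_part_slope(st$consumption, st$weights, 3, 0.3)
  s_grid <- grid_search_slope(st$consumption, st$weights, 3, 0.3,
                              s_max = 2 * rf_fit$slope)
  expect_equal(rf_fit$slope, s_grid, tolerance = 4e-4)  # grid resolution

  # no mass above threshold with a positive target is infeasible
  expect_error(fit_two_part_slope(c(1, 2), c(1, 1), 4, 0.2), "infeasible")
})

test_that("implied AAF is strictly increasing in the slope when mass exists above threshold", {
  st <- random_state(40, 55)
  slopes <- seq(0.01, 1, length.out = 25)
  aafs <- vapply(slopes, function(s)
    implied_aaf(risk_function("x", "peak_day", "partially", "acute",
                              threshold = 4, slope = s),
                st$consumption, st$weights), numeric(1))
  expect_true(all(diff(aafs) > 0))
})

test_that("incidence calibration reproduces observed volumes", {
  st <- random_state(70, 12)
  expect_equal(fit_slope_to_incidence(st$consumption, st$weights, 21,
                                      0)$absolute_slope, 0)
  # round trip from a known absolute slope
  s_true <- 0.003
  observed <- s_true * sum(st$weights * pmax(st$consumption - 21, 0))
  fit <- fit_slope_to_incidence(st$consumption, st$weights, 21, observed)
  expect_equal(fit$absolute_slope, s_true, tolerance = 1e-6)
  # expected incidents match a direct weighted-sum oracle
  oracle <- sum(st$weights * fit$absolute_slope *
                  pmax(st$consumption - 21, 0))
  expect_equal(fit$expected_incidents, observed, tolerance = 1e-6 * observed)
  expect_equal(fit$expected_incidents, oracle, tolerance = 1e-12)
  expect_error(fit_slope_to_incidence(c(1, 2), c(1, 1), 21, 5),
               "cannot be attributed")
})

test_that("the potential impact fraction obeys its defining identities", {
  rf <- risk_function("x", "peak_day", "partially", "acute",
                      threshold = 4, slope = 0.15)
  st <- random_state(60, 77)
  # identical states: exactly zero
  expect_identical(potential_impact_fraction(rf, st$consumption,
                                             st$consumption, st$weights), 0)
  # equal weights, RR before (1,3), after (1,2): 1 - 3/4
  rf2 <- risk_function("x", "peak_day", "partially", "acute",
                       threshold = 4, slope = 0.2)
  expect_equal(potential_impact_fraction(rf2, c(0, 14), c(0, 9), c(1, 1)),
               0.25)
  # inverse relation between the two directions
  a <- st$consumption; b <- pmax(a - 2, 0)
  pab <- potential_impact_fraction(rf, a, b, st$weights)
  pba <- potential_impact_fraction(rf, b, a, st$weights)
  expect_equal(1 - pab, 1 / (1 - pba), tolerance = 1e-12)
  expect_error(potential_impact_fraction(rf, a, b[-1], st$weights),
               "same weighted")
})

test_that("zero-consumption counterfactual PIF equals the implied AAF", {
  for (seed in 1:10) {
    st <- random_state(50, 1000 + seed)
    set.seed(seed)
    rf <- risk_function("x", "peak_day", "partially", "acute",
                        threshold = runif(1, 1, 8),
                        slope = runif(1, 0.01, 0.6))
    expect_equal(
      potential_impact_fraction(rf, st$consumption,
                                rep(0, 50), st$weights),
      implied_aaf(rf, st$consumption, st$weights), tolerance = 1e-12)
  }
})

test_that("the catalogue calibration anchors each cell to its configured burden", {
  pop <- synth_population(n_per_cell = 60, seed = 23)
  hc <- default_harm_config()
  rfs <- calibrate_risk_functions(pop, hc)
  rates <- generate_baseline_harms(hc)
  # the male 25-34 road-traffic function reproduces its target AAF
  rf <- rfs[["road_traffic_accidents|male|25-34"]]
  sel <- pop$sex == "male" & pop$age_band == "25-34"
  expect_equal(implied_aaf(rf, pop$peak_day_units[sel], pop$weight[sel]),
               0.37, tolerance = 1e-8)
  # wholly attributable conditions reproduce their incident volumes
  rf_w <- rfs[["alcoholic_liver_disease|male|45-54"]]
  sel2 <- pop$sex == "male" & pop$age_band == "45-54"
  expected <- sum(pop$weight[sel2] * rf_w$slope *
                    pmax(pop$mean_weekly_units[sel2] - rf_w$threshold, 0))
  observed <- rates$mortality_rate[rates$condition_id ==
      "alcoholic_liver_disease" & rates$sex == "male" &
      rates$age_band == "45-54"] * sum(pop$weight[sel2])
  expect_equal(expected, observed, tolerance = 1e-9)
})
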