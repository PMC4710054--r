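test_that("spending change matches a brute-force transaction-sum oracle", {
  pop <- synth_population(n_per_cell = 25, seed = 71)
  tx <- generate_transactions(pop, default_price_config(seed = 5))
  lvl <- structure(pop$drinker_level, names = pop$person_id)
  # no policy: zero change
  z <- spending_change(tx, tx, lvl)
  expect_equal(attr(z, "total"), 0)
  # +10% prices with inelastic demand: spending +10%
  up <- tx; up$sold_price <- up$sold_price * 1.1
  d <- spending_change(tx, up, lvl)
  base <- sum(tx$weight * tx$units * tx$sold_price) / 100
  expect_equal(attr(d, "total"), base * 0.1, tolerance = 1e-9)
  # brute-force oracle on a random before/after pair
  set.seed(72)
  aft <- tx
  aft$sold_price <- aft$sold_price * runif(nrow(tx), 0.9, 1.3)
  aft$units <- aft$units * runif(nrow(tx), 0.7, 1.1)
  d2 <- spending_change(tx, aft, lvl)
  oracle <- sum(aft$weight * aft$units * aft$sold_price -
                  tx$weight * tx$units * tx$sold_price) / 100
  expect_equal(attr(d2, "total"), oracle, tolerance = 1e-9)
  expect_error(spending_change(tx[-1, ], tx, lvl), "aligned")
})

test_that("revenue decomposition is exact and VAT is computed on inclusive sales", {
  # a single 117.50 GBP sale with zero duty: VAT 17.50, retailer 100
  tx <- data.frame(person_id = "x", category = "beer_off_low", units = 1,
                   usual_price = 11750, sold_price = 11750, weight = 1,
                   stringsAsFactors = FALSE)
  params <- default_valuation_params(duty_per_unit = c(beer = 0, wine = 0,
                                                       spirit = 0, rtd = 0))
  d <- revenue_decomposition(tx, params)
  expect_equal(d$sales, 117.5)
  expect_equal(d$vat, 17.5, tolerance = 1e-9)
  expect_equal(d$retailer, 100, tolerance = 1e-9)
  # zero sales: all-zero table
  d0 <- revenue_decomposition(tx[0, ], params)
  expect_equal(nrow(d0), 0)
  # components always re-sum to sales exactly
  pop <- synth_population(n_per_cell = 25, seed = 73)
  txs <- generate_transactions(pop, default_price_config(seed = 6))
  dd <- revenue_decomposition(txs)
  expect_equal(dd$retailer + dd$duty + dd$vat, dd$sales, tolerance = 1e-9)
})

test_that("outcome valuation applies the QALY values and is linear", {
  params <- default_valuation_params()
  zero <- value_outcomes(list(qalys_gained = 0, cost_change = 0),
                         list(victim_qalys = 0, cost_change = 0),
                         list(absence_cost_change = 0,
                              unemployment_cost_change = 0), params)
  expect_equal(zero$total, 0)
  # 10 health QALYs at 50,000 GBP
  h <- value_outcomes(list(qalys_gained = 10, cost_change = 0),
                      list(victim_qalys = 0, cost_change = 0),
                      list(absence_cost_change = 0,
                           unemployment_cost_change = 0), params)
  expect_equal(h$health, 500000)
  # 2 crime QALYs at 81,000 GBP
  cr <- value_outcomes(list(qalys_gained = 0, cost_change = 0),
                       list(victim_qalys = 2, cost_change = 0),
                       list(absence_cost_change = 0,
                            unemployment_cost_change = 0), params)
  expect_equal(cr$crime, 162000)
  # linearity: doubling all inputs doubles the total
  a <- value_outcomes(list(qalys_gained = 3, cost_change = -1000),
                      list(victim_qalys = 1, cost_change = -500),
                      list(absence_cost_change = -200,
                           unemployment_cost_change = -800), params)
  b <- value_outcomes(list(qalys_gained = 6, cost_change = -2000),
                      list(victim_qalys = 2, cost_change = -1000),
                      list(absence_cost_change = -400,
                           unemployment_cost_change = -1600), params)
  expect_equal(b$total, 2 * a$total, tolerance = 1e-12)
})

test_that("the comparison table recomputes channel sums per policy", {
  cfg <- default_model_config(n_per_cell = 25, seed = 77, horizon = 5)
  bl <- build_baseline(cfg)
  pols <- list(null = policy("general_price_change", "null", percent = 0),
               mup = policy("minimum_unit_price", "mup50", floor = 50))
  out <- compare_policies(pols, baseline = bl)
  tab <- out$comparison
  expect_equal(nrow(tab), 2)
  expect_equal(tab$policy, c("null", "mup"))
  # the null policy is a row of (near-)zeros
  expect_equal(tab$consumption_change_pct[1], 0, tolerance = 1e-9)
  expect_equal(tab$total_value_gbp[1], 0, tolerance = 1e-6)
  # row values equal independently recomputed channel sums
  r <- out$results$mup
  expect_equal(tab$total_value_gbp[2],
               r$value$health + r$value$crime + r$value$workplace,
               tolerance = 1e-9)
  expect_equal(tab$deaths_averted[2], r$deaths_averted)
  # heterogeneous horizons are rejected
  r2 <- out$results$mup; r2$horizon <- 7
  expect_error(build_policy_comparison(list(a = r, b = r2)),
               "different horizons")
})

test_that("minimum-price spending change is non-negative per subgroup under inelastic demand", {
  pop <- synth_population(n_per_cell = 25, seed = 79)
  tx <- generate_transactions(pop, default_price_config(seed = 7))
  lvl <- structure(pop$drinker_level, names = pop$person_id)
  after <- apply_minimum_unit_price(tx, 60)
  d <- spending_change(tx, after, lvl)
  expect_true(all(d$spending_change_gbp >= -1e-12))
})
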