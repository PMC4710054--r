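test_that("crime volume changes follow the PIF and conserve category totals", {
  pop <- synth_population(n_per_cell = 40, seed = 51)
  cats <- default_crime_catalogue()
  expect_equal(nrow(cats), 20)
  rfs <- calibrate_crime_risk_functions(pop, cats)
  ow <- default_offender_weights(cats)
  # apportionment weights sum to 1 per category
  sums <- vapply(split(ow$weight, ow$category_id), sum, numeric(1))
  expect_equal(unname(sums), rep(1, 20), tolerance = 1e-12)

  # no consumption change: zero crime change
  none <- crime_pif_and_volumes(pop, pop, rfs, cats, ow)
  expect_equal(none$total_offence_change, 0)

  # a 30% cut in peak consumption averts offences
  cut <- pop; cut$peak_day_units <- cut$peak_day_units * 0.7
  res <- crime_pif_and_volumes(pop, cut, rfs, cats, ow)
  expect_lt(res$total_offence_change, 0)
  # subgroup changes sum to the category totals exactly
  sub_tot <- vapply(split(res$by_subgroup$change,
                          res$by_subgroup$category_id), sum, numeric(1))
  expect_equal(unname(sub_tot[res$by_category$category_id]),
               res$by_category$change, tolerance = 1e-9)

  # zero-counterfactual identity: reduction = AAF x apportioned baseline
  zero <- pop; zero$peak_day_units <- 0
  rz <- crime_pif_and_volumes(pop, zero, rfs, cats, ow)
  aaf_direct <- sum(vapply(seq_len(nrow(rz$by_subgroup)), function(i) {
    row <- rz$by_subgroup[i, ]
    rz$by_subgroup$baseline[i] * row$pif
  }, numeric(1)))
  expect_equal(-rz$total_offence_change, aaf_direct, tolerance = 1e-9)

  expect_error(crime_pif_and_volumes(pop, cut, rfs, cats,
                                     ow[ow$category_id != "wounding_1", ]),
               "missing")
})

test_that("unemployment calibration reproduces the 6.9% work-probability reduction", {
  pop <- synth_population(n_per_cell = 80, seed = 61)
  params <- default_workplace_params()
  rfs <- calibrate_unemployment(pop, params)
  # male target is the headline 6.9%
  expect_equal(implied_work_reduction(rfs$male, pop, params), 0.069,
               tolerance = 1e-6)
  # female target adjusted by the participation-rate ratio (reweighting
  # oracle: recompute the ratio directly from the parameter table)
  part <- tapply(params$cells$participation, params$cells$sex, mean)
  expect_equal(implied_work_reduction(rfs$female, pop, params),
               0.069 * unname(part["female"] / part["male"]),
               tolerance = 1e-6)
  # zero target: flat function, zero effect
  p0 <- params; p0$work_reduction_target <- 0
  rf0 <- calibrate_unemployment(pop, p0)
  expect_equal(rf0$male$slope, 0)
})

test_that("unemployment effects are zero outside the harmful group and value at salary", {
  pop <- synth_population(n_per_cell = 60, seed = 63)
  params <- default_workplace_params()
  rfs <- calibrate_unemployment(pop, params)
  # the function is flat below the harmful boundary: moderate and
  # hazardous drinkers all sit at RR = 1
  nh <- pop$drinker_level != "harmful" &
    pop$age_band %in% params$working_bands
  for (s in sexes()) {
    sel <- nh & pop$sex == s
    expect_true(all(evaluate_rr(rfs[[s]],
                                pop$mean_weekly_units[sel]) == 1))
  }
  # no consumption change: zero
  z <- unemployment_change(pop, pop, rfs, params)
  expect_equal(attr(z, "total_persons"), 0)
  # all harmful drinkers dropping below threshold averts the full
  # attributable share (zero-counterfactual identity per cell)
  zero <- pop; zero$mean_weekly_units <- 0
  full <- unemployment_change(pop, zero, rfs, params)
  expect_lt(attr(full, "total_persons"), 0)
  expect_equal(full$cost_change, full$persons_change * full$salary,
               tolerance = 1e-12)
})

test_that("absence changes scale baseline days by the PIF with working-age scope", {
  pop <- synth_population(n_per_cell = 50, seed = 65)
  params <- default_workplace_params()
  rfs <- calibrate_absence_risk_functions(pop, params)
  same <- absence_change(pop, pop, rfs, params)
  expect_equal(attr(same, "total_days"), 0)
  cut <- pop; cut$peak_day_units <- cut$peak_day_units * 0.6
  res <- absence_change(pop, cut, rfs, params)
  expect_lt(attr(res, "total_days"), 0)
  # only working-age bands appear in the table at all
  expect_true(all(res$age_band %in% params$working_bands))
  # arithmetic: days change = -baseline x PIF per cell
  i <- which(res$sex == "male" & res$age_band == "25-34")
  sel <- pop$sex == "male" & pop$age_band == "25-34"
  rf <- rfs[["male|16-25"]]
  pif <- potential_impact_fraction(rf, pop$peak_day_units[sel],
                                   cut$peak_day_units[sel],
                                   pop$weight[sel])
  expect_equal(res$days_change[i], -res$baseline_absence_days[i] * pif,
               tolerance = 1e-12)
})
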