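# End-to-end policy simulation ----------------------------------------------

#' Bundle the model configuration
#'
#' Collects every configurable input of the simulator: classification
#' thresholds, synthetic-data configurations, elasticity matrices, the
#' binge (peak-from-mean) model, the harm catalogue, life table, crime and
#' workplace parameters, valuation parameters, the chronic-harm lag and the
#' projection horizon.
#'
#' @param n_per_cell Individuals per sex x age band in the synthetic
#'   population.
#' @param seed Master seed; the population and price seeds are derived from
#'   it.
#' @param horizon Projection horizon in years.
#' @return List of class `model_config`.
#' @export
default_model_config <- function(n_per_cell = 200, seed = 42, horizon = 10) {
  pop <- default_population_config(n_per_cell = n_per_cell, seed = seed)
  structure(list(
    thresholds = default_thresholds(),
    population = pop,
    price = default_price_config(seed = seed + 1L),
    elasticities = default_elasticities(),
    binge = pop$binge,
    harm = default_harm_config(),
    life_table = default_life_table(),
    crime = default_crime_catalogue(),
    offender_weights = NULL,   # built lazily from crime catalogue
    workplace = default_workplace_params(),
    valuation = default_valuation_params(),
    lag = lag_model(10),
    horizon = horizon,
    seed = seed), class = "model_config")
}

#' Generate baseline data and calibrate every risk function
#'
#' Runs the synthetic generators (population, transactions, price
#' calibration) and calibrates the health, crime, absence and unemployment
#' risk functions on the baseline population.  Calibration is done once per
#' population and shared across policies.
#'
#' @param config A [default_model_config()] list.
#' @return List of class `model_baseline`: individuals (with subgroups),
#'   transactions, and the calibrated risk-function sets.
#' @export
build_baseline <- function(config = default_model_config()) {
  individuals <- generate_population(config$population)
  individuals <- assign_subgroups(individuals, config$thresholds)
  transactions <- generate_transactions(individuals, config$price)
  transactions <- calibrate_price_distribution(transactions,
                                               config$price$calibration)
  ow <- if (is.null(config$offender_weights))
    default_offender_weights(config$crime) else config$offender_weights
  structure(list(
    individuals = individuals,
    transactions = transactions,
    health_rfs = calibrate_risk_functions(individuals, config$harm),
    crime_rfs = calibrate_crime_risk_functions(individuals, config$crime),
    absence_rfs = calibrate_absence_risk_functions(individuals,
                                                   config$workplace),
    unemployment_rfs = calibrate_unemployment(individuals,
                                              config$workplace),
    offender_weights = ow,
    config = config), class = "model_baseline")
}

# weighted percent change in mean consumption, overall and per level
consumption_change_summary <- function(before, after) {
  pct <- function(sel) {
    b <- sum(before$weight[sel] * before$mean_weekly_units[sel])
    a <- sum(after$weight[sel] * after$mean_weekly_units[sel])
    if (b <= 0) 0 else 100 * (a - b) / b
  }
  c(all = pct(rep(TRUE, nrow(before))),
    moderate = pct(before$drinker_level == "moderate"),
    hazardous = pct(before$drinker_level == "hazardous"),
    harmful = pct(before$drinker_level == "harmful"))
}

#' Simulate one policy end to end
#'
#' Pricing policies: the policy transforms the transaction price
#' distribution; the per-segment vectors of 16 mean percent price changes
#' feed the segment elasticity matrices, giving 16 percent consumption
#' changes that are applied to the individual consumption records (means
#' floored at zero, shares re-normalised, peaks updated through the linear
#' peak-from-mean model); transaction volumes are rescaled consistently.
#' What-if policies (`relative_consumption_change`) skip the price stage
#' and scale consumption directly.  The revised consumption states then
#' drive, via the calibrated risk functions and the potential impact
#' fraction: a ten-year age-cohort health projection (linear lag on chronic
#' harms), per-annum crime, absence and unemployment changes, and the
#' monetary valuation with retailer/duty/VAT revenue accounting.
#'
#' @param pol A [policy()] (or a list of policies applied sequentially).
#' @param baseline A [build_baseline()] object.
#' @param coverage Fraction of each demand segment affected.
#' @return List of class `policy_result`.
#' @export
simulate_policy <- function(pol, baseline, coverage = 1) {
  config <- baseline$config
  ind0 <- baseline$individuals
  tx0 <- baseline$transactions
  seg <- demand_segments(ind0)
  lvl <- structure(ind0$drinker_level, names = ind0$person_id)

  is_rel <- function(p) inherits(p, "policy") &&
    p$kind == "relative_consumption_change"
  pols <- if (inherits(pol, "policy")) list(pol) else pol
  rel <- vapply(pols, is_rel, logical(1))

  if (any(rel)) {
    pct <- sum(vapply(pols[rel], function(p) p$percent, numeric(1)))
    ind1 <- apply_relative_change(ind0, pct, config$binge)
    dc <- list(moderate = rep(pct, 16), hazardous_harmful = rep(pct, 16))
    names(dc$moderate) <- names(dc$hazardous_harmful) <-
      beverage_categories()
    tx1 <- tx0
    price_changes <- list(moderate = stats::setNames(numeric(16),
                                                     beverage_categories()),
                          hazardous_harmful =
                            stats::setNames(numeric(16),
                                            beverage_categories()))
  } else {
    tx_priced <- apply_policy(tx0, pol)
    price_changes <- mean_price_change_vector(tx0, tx_priced, seg)
    dc <- lapply(config$elasticities, function(E)
      consumption_change_vector(price_changes[[attr(E, "segment")]], E))
    names(dc) <- names(config$elasticities)
    old_mean <- ind0$mean_weekly_units
    ind1 <- apply_consumption_change(ind0, dc, coverage = coverage)
    ind1 <- update_peak(ind1, old_mean, ind1$mean_weekly_units,
                        config$binge)
    tx1 <- tx_priced
  }
  # rescale transaction volumes by the consumption change of the
  # transaction's category and the purchaser's segment
  segv <- unname(seg[tx1$person_id])
  cat_idx <- match(tx1$category, beverage_categories())
  dcv <- ifelse(segv == "moderate", dc$moderate[cat_idx],
                dc$hazardous_harmful[cat_idx])
  tx1$units <- tx1$units * pmax(1 + coverage * dcv / 100, 0)

  cons_pct <- consumption_change_summary(ind0, ind1)

  # purchasing and revenue
  spend <- spending_change(tx0, tx1, lvl)
  rev0 <- revenue_decomposition(tx0, config$valuation)
  rev1 <- revenue_decomposition(tx1, config$valuation)
  base_spend <- sum(rev0$sales)
  spend_pct <- if (base_spend > 0)
    100 * attr(spend, "total") / base_spend else 0

  # health projection
  rates <- generate_baseline_harms(config$harm)
  cells <- expand.grid(sex = sexes(), age_band = age_bands(),
                       stringsAsFactors = FALSE)
  deaths <- adm <- qalys <- hcost <- 0
  for (i in seq_len(nrow(cells))) {
    s <- cells$sex[i]; band <- cells$age_band[i]
    sel <- ind0$sex == s & ind0$age_band == band
    if (!any(sel)) next
    cohort <- sum(ind0$weight[sel])
    cr <- rates[rates$sex == s & rates$age_band == band, ]
    cr$pif <- vapply(seq_len(nrow(cr)), function(j) {
      rf <- baseline$health_rfs[[paste(cr$condition_id[j], s, band,
                                       sep = "|")]]
      if (is.null(rf)) return(0)
      before <- if (rf$basis == "mean_weekly")
        ind0$mean_weekly_units[sel] else ind0$peak_day_units[sel]
      after <- if (rf$basis == "mean_weekly")
        ind1$mean_weekly_units[sel] else ind1$peak_day_units[sel]
      potential_impact_fraction(rf, before, after, ind0$weight[sel])
    }, numeric(1))
    cr$timing <- config$harm$conditions$timing[
      match(cr$condition_id, config$harm$conditions$condition_id)]
    pr <- project_cohort(cohort, s, band, cr, config$life_table,
                         horizon = config$horizon, lag = config$lag,
                         qaly_rate = config$valuation$qaly_rate,
                         cost_rate = config$valuation$cost_rate)
    deaths <- deaths + pr$total_deaths_averted
    adm <- adm + pr$total_admissions_averted
    qalys <- qalys + pr$total_qalys
    hcost <- hcost + pr$total_cost_change
  }

  # crime, absence, unemployment (per-annum changes, accrued over the
  # horizon with channel discounting; acute, so no lag)
  crime <- crime_pif_and_volumes(ind0, ind1, baseline$crime_rfs,
                                 config$crime, baseline$offender_weights)
  absn <- absence_change(ind0, ind1, baseline$absence_rfs, config$workplace)
  unemp <- unemployment_change(ind0, ind1, baseline$unemployment_rfs,
                               config$workplace)
  hz <- config$horizon
  ann_cost <- function(x, r) discount_stream(rep(x, hz), r)
  crime_qalys <- ann_cost(crime$total_victim_qalys,
                          config$valuation$qaly_rate)
  crime_cost <- ann_cost(crime$total_cost_change,
                         config$valuation$cost_rate)
  absence_cost <- ann_cost(attr(absn, "total_cost"),
                           config$valuation$cost_rate)
  unemp_cost <- ann_cost(attr(unemp, "total_cost"),
                         config$valuation$cost_rate)

  value <- value_outcomes(
    health = list(qalys_gained = qalys, cost_change = hcost),
    crime = list(victim_qalys = crime_qalys, cost_change = crime_cost),
    workplace = list(absence_cost_change = absence_cost,
                     unemployment_cost_change = unemp_cost),
    params = config$valuation)

  structure(list(
    policy = pol,
    horizon = config$horizon,
    price_changes = price_changes,
    consumption_changes = dc,
    consumption_change_pct = cons_pct,
    spending_change_pct = spend_pct,
    spending_change_gbp = attr(spend, "total"),
    spending_by_subgroup = spend,
    retailer_revenue_change_gbp = sum(rev1$retailer) - sum(rev0$retailer),
    duty_vat_change_gbp = sum(rev1$duty + rev1$vat) -
      sum(rev0$duty + rev0$vat),
    revenue_before = rev0, revenue_after = rev1,
    deaths_averted = deaths, admissions_averted = adm,
    health_qalys = qalys, health_cost_change = hcost,
    crime = crime, crime_qalys = crime_qalys,
    crime_cost_change = crime_cost,
    absence = absn, unemployment = unemp,
    value = value), class = "policy_result")
}

#' @export
print.policy_result <- function(x, ...) {
  nm <- if (inherits(x$policy, "policy")) x$policy$name else
    paste(vapply(x$policy, function(p) p$name, character(1)),
          collapse = " + ")
  cat(sprintf("<policy_result> %s (%d-year horizon)\n", nm, x$horizon))
  cat(sprintf("  consumption: %+.2f%% overall (moderate %+.2f%%, harmful %+.2f%%)\n",
              x$consumption_change_pct["all"],
              x$consumption_change_pct["moderate"],
              x$consumption_change_pct["harmful"]))
  cat(sprintf("  spending: %+.2f%% (GBP %+.0f); retailer %+.0f, duty+VAT %+.0f\n",
              x$spending_change_pct, x$spending_change_gbp,
              x$retailer_revenue_change_gbp, x$duty_vat_change_gbp))
  cat(sprintf("  deaths averted %.2f, admissions averted %.1f, health QALYs %.1f\n",
              x$deaths_averted, x$admissions_averted, x$health_qalys))
  cat(sprintf("  offences change %.1f/yr, unemployment change %.1f persons/yr\n",
              x$crime$total_offence_change,
              attr(x$unemployment, "total_persons")))
  print(x$value)
  invisible(x)
}

#' @export
summary.policy_result <- function(object, ...) {
  print(object)
  invisible(object)
}

#' Simulate and compare a set of policies
#'
#' Builds (or reuses) a baseline, simulates every policy against it and
#' assembles the comparison table.
#'
#' @param policies Named list of policies (default: the full
#'   [policy_library()]).
#' @param baseline A [build_baseline()] object, or NULL to build one from
#'   `config`.
#' @param config Used only when `baseline` is NULL.
#' @return A list: `results` (per-policy `policy_result`s) and `comparison`
#'   (the [build_policy_comparison()] table).
#' @export
compare_policies <- function(policies = policy_library(), baseline = NULL,
                             config = default_model_config()) {
  if (is.null(baseline)) baseline <- build_baseline(config)
  results <- lapply(policies, simulate_policy, baseline = baseline)
  list(results = results, comparison = build_policy_comparison(results))
}
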