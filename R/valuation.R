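# Monetary valuation and revenue accounting ----------------------------------

#' Default valuation parameters
#'
#' A health QALY is valued at 50,000 GBP and a crime-victim QALY at 81,000
#' GBP; VAT at 17.5 % (levied on the net price, i.e. computed from
#' VAT-inclusive retail sales as `sales * r / (1 + r)`); per-unit duty by
#' beverage type; QALYs discounted at 3.5 %/year and health-care costs at
#' 1.5 %/year.  All amounts at the model's base-year price level, no
#' inflation adjustment.
#'
#' @param health_qaly_value,crime_qaly_value GBP per QALY.
#' @param vat_rate Ad-valorem VAT rate on the net price.
#' @param duty_per_unit Named vector, pence per unit of ethanol by beverage
#'   (beer, wine, spirit, rtd).
#' @param qaly_rate,cost_rate Annual discount rates.
#' @return List of class `valuation_params`.
#' @export
default_valuation_params <- function(health_qaly_value = 50000,
                                     crime_qaly_value = 81000,
                                     vat_rate = 0.175,
                                     duty_per_unit = c(beer = 16, wine = 18,
                                                       spirit = 22, rtd = 26),
                                     qaly_rate = 0.035, cost_rate = 0.015) {
  stopifnot(health_qaly_value >= 0, crime_qaly_value >= 0, vat_rate >= 0,
            all(duty_per_unit >= 0))
  structure(list(health_qaly_value = health_qaly_value,
                 crime_qaly_value = crime_qaly_value, vat_rate = vat_rate,
                 duty_per_unit = duty_per_unit, qaly_rate = qaly_rate,
                 cost_rate = cost_rate),
            class = "valuation_params")
}

#' Consumer spending change by subgroup and sector
#'
#' Per drinker-level subgroup and sector, the change in the weighted value
#' of purchasing: `sum(weight * units * sold_price)` after minus before,
#' computed in pence and reported in GBP.
#'
#' @param before,after Aligned transaction tables (same rows; units and/or
#'   prices differ).
#' @param level_of Named character vector person_id -> drinker level.
#' @return Data frame: drinker_level, sector, spending change (GBP), with
#'   the total as an attribute.
#' @export
spending_change <- function(before, after, level_of) {
  if (nrow(before) != nrow(after) ||
      !identical(before$person_id, after$person_id))
    stop("before/after transaction tables are not aligned", call. = FALSE)
  sector <- ifelse(grepl("_on_", before$category), "on_trade", "off_trade")
  lvl <- unname(level_of[before$person_id])
  val_b <- before$weight * before$units * before$sold_price
  val_a <- after$weight * after$units * after$sold_price
  d <- stats::aggregate((val_a - val_b) / 100,
                        list(drinker_level = lvl, sector = sector), sum)
  names(d)[3] <- "spending_change_gbp"
  attr(d, "total") <- sum(d$spending_change_gbp)
  d
}

#' Retailer / duty / VAT decomposition of sales
#'
#' Retail prices are VAT-inclusive, so VAT = sales * r / (1 + r); duty =
#' units sold x per-unit duty for the beverage type; retailer income is the
#' remainder.  The three components re-sum to sales exactly.  Duty
#' exceeding net-of-VAT sales triggers a warning (possible with extreme
#' synthetic prices) but the identity is preserved.
#'
#' @param transactions Transaction table (sold prices in pence/unit).
#' @param params A [default_valuation_params()] list.
#' @return Data frame per sector x beverage type: units, sales, VAT, duty,
#'   retailer (all GBP except units).
#' @export
revenue_decomposition <- function(transactions,
                                  params = default_valuation_params()) {
  if (nrow(transactions) == 0)
    return(data.frame(sector = character(0), beverage = character(0),
                      units = numeric(0), sales = numeric(0),
                      vat = numeric(0), duty = numeric(0),
                      retailer = numeric(0)))
  bev <- sub("_.*", "", transactions$category)
  miss <- setdiff(unique(bev), names(params$duty_per_unit))
  if (length(miss))
    stop("duty table missing beverage type(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  sector <- ifelse(grepl("_on_", transactions$category), "on_trade",
                   "off_trade")
  units <- transactions$weight * transactions$units
  sales <- units * transactions$sold_price / 100
  d <- stats::aggregate(cbind(units = units, sales = sales),
                        list(sector = sector, beverage = bev), sum)
  r <- params$vat_rate
  d$vat <- d$sales * r / (1 + r)
  d$duty <- d$units * params$duty_per_unit[d$beverage] / 100
  d$retailer <- d$sales - d$vat - d$duty
  if (any(d$retailer < 0))
    warning("duty exceeds net sales for some rows (extreme prices)")
  d
}

#' Monetise the three harm channels
#'
#' Health = health-care cost change + health QALYs x the health QALY value;
#' crime = justice-system cost change + victim QALYs x the crime QALY
#' value; workplace = absence and unemployment changes valued at salary.
#' Streams are expected already discounted per the channel conventions;
#' valuation itself is linear.  Sign convention: negative = saving/harm
#' reduction in the cost lines, positive QALY counts = gains.
#'
#' @param health List with `qalys_gained` and `cost_change` (GBP, negative
#'   = saving).
#' @param crime List with `victim_qalys` and `cost_change`.
#' @param workplace List with `absence_cost_change` and
#'   `unemployment_cost_change`.
#' @param params A [default_valuation_params()] list.
#' @return List of class `cost_benefit_summary` with per-channel and grand
#'   totals (GBP; positive = net benefit).
#' @export
value_outcomes <- function(health, crime, workplace,
                           params = default_valuation_params()) {
  health_value <- health$qalys_gained * params$health_qaly_value -
    health$cost_change
  crime_value <- crime$victim_qalys * params$crime_qaly_value -
    crime$cost_change
  workplace_value <- -(workplace$absence_cost_change +
                         workplace$unemployment_cost_change)
  structure(list(health = health_value, crime = crime_value,
                 workplace = workplace_value,
                 total = health_value + crime_value + workplace_value),
            class = "cost_benefit_summary")
}

#' @export
print.cost_benefit_summary <- function(x, ...) {
  cat("Monetised harm reductions (GBP, positive = benefit):\n")
  cat(sprintf("  health    %14.0f\n", x$health))
  cat(sprintf("  crime     %14.0f\n", x$crime))
  cat(sprintf("  workplace %14.0f\n", x$workplace))
  cat(sprintf("  total     %14.0f\n", x$total))
  invisible(x)
}

#' Build a policy comparison table
#'
#' One row per simulated policy: percent consumption change (overall,
#' moderate, harmful), percent and absolute spending change, retailer and
#' duty+VAT revenue changes, deaths averted, health and crime QALYs, and
#' monetised changes by channel.  Every column is recomputed from the
#' stored per-policy results, not copied from any printed source.
#'
#' @param results Named list of `policy_result` objects (all with the same
#'   horizon).
#' @return Data frame of class `policy_comparison`.
#' @export
build_policy_comparison <- function(results) {
  stopifnot(length(results) >= 1)
  hz <- vapply(results, function(r) r$horizon, numeric(1))
  if (length(unique(hz)) != 1)
    stop("policies were projected over different horizons", call. = FALSE)
  rows <- lapply(names(results), function(nm) {
    r <- results[[nm]]
    data.frame(policy = nm,
               consumption_change_pct = r$consumption_change_pct["all"],
               consumption_change_pct_moderate =
                 r$consumption_change_pct["moderate"],
               consumption_change_pct_harmful =
                 r$consumption_change_pct["harmful"],
               spending_change_pct = r$spending_change_pct,
               spending_change_gbp = r$spending_change_gbp,
               retailer_revenue_change_gbp = r$retailer_revenue_change_gbp,
               duty_vat_change_gbp = r$duty_vat_change_gbp,
               deaths_averted = r$deaths_averted,
               health_qalys = r$health_qalys,
               crime_qalys = r$crime_qalys,
               health_value_gbp = r$value$health,
               crime_value_gbp = r$value$crime,
               workplace_value_gbp = r$value$workplace,
               total_value_gbp = r$value$total,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("policy_comparison", "data.frame")
  out
}

#' @export
print.policy_comparison <- function(x, ...) {
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], function(v) signif(v, 4))
  print(y, row.names = FALSE)
  invisible(x)
}
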