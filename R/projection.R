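# Ten-year age-cohort projection with a linear lag on chronic harms ----------

#' Linear lag model for chronic harms
#'
#' Chronic risk reductions are realised linearly over `years_to_full_effect`
#' years: the fraction of full effect at year t is `min(t / L, 1)`, so 1/10
#' at year 1, 2/10 at year 2, ..., full effect from year 10 with the
#' default L = 10.  Acute harms bypass the lag entirely.
#'
#' @param years_to_full_effect Positive integer (default 10).
#' @return Object of class `lag_model`.
#' @export
lag_model <- function(years_to_full_effect = 10) {
  stopifnot(years_to_full_effect >= 1)
  structure(list(years_to_full_effect = years_to_full_effect,
                 shape = "linear"), class = "lag_model")
}

#' Lag fraction at a model year
#'
#' @param year Model year (>= 0; fraction(0) = 0).
#' @param lag A [lag_model()].
#' @param timing `"chronic"` (lagged) or `"acute"` (full effect from year
#'   1).
#' @return Fraction of full effect in [0, 1].
#' @export
lag_fraction <- function(year, lag = lag_model(), timing = "chronic") {
  if (any(year < 0)) stop("year must be non-negative", call. = FALSE)
  if (timing == "acute") return(ifelse(year >= 1, 1, 0))
  pmin(year / lag$years_to_full_effect, 1)
}

#' Annual harm rates under the policy (A) and do-nothing (B) futures
#'
#' Future B is steady state: the baseline rate every year.  Future A scales
#' the baseline by `1 - lag_fraction(t) * pif` for chronic harms and by
#' `1 - pif` (no lag) for acute harms.
#'
#' @param baseline_rate Baseline annual rate (per person-year).
#' @param pif Potential impact fraction (<= 1).
#' @param year Model year (>= 1).
#' @param timing `"chronic"` or `"acute"`.
#' @param lag A [lag_model()].
#' @return List with elements `A` and `B`.
#' @export
annual_rates <- function(baseline_rate, pif, year, timing,
                         lag = lag_model()) {
  if (is.na(baseline_rate))
    stop("baseline rate missing", call. = FALSE)
  stopifnot(pif <= 1)
  lf <- lag_fraction(year, lag, timing)
  list(A = baseline_rate * (1 - lf * pif), B = baseline_rate)
}

#' Default synthetic life table
#'
#' All-cause annual mortality by sex and single year of age (Gompertz-type
#' increase, male excess) and population-average utility weights declining
#' with age, standing in for national interim life tables joined to
#' population EQ-5D norms.
#'
#' @param max_age Oldest age covered.
#' @return Data frame: sex, age, mortality, utility.
#' @export
default_life_table <- function(max_age = 105) {
  grid <- expand.grid(age = 0:max_age, sex = sexes(),
                      stringsAsFactors = FALSE)
  a <- ifelse(grid$sex == "male", 6.5e-5, 4.5e-5)
  b <- 0.088
  grid$mortality <- pmin(a * exp(b * grid$age), 0.7)
  grid$utility <- pmax(0.95 - 0.0028 * pmax(grid$age - 20, 0), 0.4)
  grid[, c("sex", "age", "mortality", "utility")]
}

# representative (midpoint) single age for each band
band_mid_age <- function(band) {
  c("11-15" = 13, "16-17" = 16.5, "18-24" = 21, "25-34" = 30, "35-44" = 40,
    "45-54" = 50, "55-64" = 60, "65-74" = 70, "75+" = 80)[band]
}

# discounted quality-adjusted life expectancy from a given age (life-table
# recursion; utilities applied per life-year, end-of-year discounting)
discounted_qale <- function(life_table, sex, age, rate) {
  lt <- life_table[life_table$sex == sex & life_table$age >= round(age), ]
  lt <- lt[order(lt$age), ]
  if (nrow(lt) == 0) return(0)
  surv <- cumprod(1 - lt$mortality)
  sum(surv * lt$utility / (1 + rate)^seq_len(nrow(lt)))
}

#' Discount a stream of annual values to present value
#'
#' End-of-year convention: the year-t value is divided by `(1 + rate)^t`,
#' so a year-1 value is discounted one period.
#'
#' @param values_by_year Numeric vector, element t = value in year t.
#' @param annual_rate Discount rate (>= 0), e.g. 0.035.
#' @return Present value (scalar).
#' @export
discount_stream <- function(values_by_year, annual_rate) {
  stopifnot(annual_rate >= 0)
  if (length(values_by_year) == 0) return(0)
  sum(values_by_year / (1 + annual_rate)^seq_along(values_by_year))
}

#' Project a subgroup cohort over the horizon
#'
#' Year-by-year comparison of Future A (policy) and Future B (do-nothing,
#' steady-state baseline rates).  The cohort ages one year per model year;
#' within-year mortality is additive across conditions plus life-table
#' other-cause mortality, capped at 1.  Deaths averted each year are the
#' Future-B minus Future-A condition deaths; each averted death accrues the
#' discounted quality-adjusted life expectancy remaining at that age.
#' Prevalent cases (proxied by person-specific hospitalisations) accrue a
#' per-case utility decrement and annual treatment cost.  QALYs are
#' discounted at `qaly_rate`, costs at `cost_rate`.
#'
#' @param cohort_size Weighted persons in the subgroup.
#' @param sex,age_band Subgroup identity.
#' @param conditions Data frame: condition_id, timing, pif, mortality_rate,
#'   admission_rate, unit_cost, utility_decrement.
#' @param life_table See [default_life_table()].
#' @param horizon Years projected (default 10).
#' @param lag A [lag_model()].
#' @param qaly_rate,cost_rate Annual discount rates.
#' @return List of class `projection_result`: per-year vectors of deaths
#'   averted and admissions averted, discounted QALYs gained and health-care
#'   cost change, plus cumulative totals.
#' @export
project_cohort <- function(cohort_size, sex, age_band, conditions,
                           life_table = default_life_table(), horizon = 10,
                           lag = lag_model(), qaly_rate = 0.035,
                           cost_rate = 0.015) {
  stopifnot(horizon >= 1)
  age0 <- band_mid_age(age_band)
  if (age0 + horizon > max(life_table$age))
    stop("horizon extends beyond life-table coverage", call. = FALSE)
  nA <- nB <- cohort_size
  deaths_av <- adm_av <- qaly_gain <- cost_change <- numeric(horizon)
  for (t in seq_len(horizon)) {
    age <- age0 + (t - 1)
    other <- life_table$mortality[life_table$sex == sex &
                                    life_table$age == round(age)][1]
    rates <- lapply(seq_len(nrow(conditions)), function(i)
      annual_rates(conditions$mortality_rate[i], conditions$pif[i], t,
                   conditions$timing[i], lag))
    mortA <- vapply(rates, `[[`, numeric(1), "A")
    mortB <- vapply(rates, `[[`, numeric(1), "B")
    dA <- nA * mortA
    dB <- nB * mortB
    deaths_av[t] <- sum(dB) - sum(dA)
    admA <- nA * conditions$admission_rate *
      (1 - lag_fraction(t, lag, "chronic") * conditions$pif *
         (conditions$timing == "chronic") -
         conditions$pif * (conditions$timing == "acute"))
    admB <- nB * conditions$admission_rate
    adm_av[t] <- sum(admB) - sum(admA)
    qale <- discounted_qale(life_table, sex, age, qaly_rate)
    morb_qaly <- sum((admB - admA) * conditions$utility_decrement)
    qaly_gain[t] <- deaths_av[t] * qale / (1 + qaly_rate)^(t - 1) +
      morb_qaly / (1 + qaly_rate)^t
    cost_change[t] <- sum((admA - admB) * conditions$unit_cost) /
      (1 + cost_rate)^t
    nA <- nA * max(0, 1 - min(sum(mortA) + other, 1))
    nB <- nB * max(0, 1 - min(sum(mortB) + other, 1))
  }
  structure(list(sex = sex, age_band = age_band, horizon = horizon,
                 deaths_averted = deaths_av, admissions_averted = adm_av,
                 qalys_gained = qaly_gain, cost_change = cost_change,
                 total_deaths_averted = sum(deaths_av),
                 total_admissions_averted = sum(adm_av),
                 total_qalys = sum(qaly_gain),
                 total_cost_change = sum(cost_change)),
            class = "projection_result")
}

#' @export
print.projection_result <- function(x, ...) {
  cat(sprintf("<projection_result> %s %s, %d-year horizon\n",
              x$sex, x$age_band, x$horizon))
  cat(sprintf("  deaths averted %.2f, admissions averted %.1f\n",
              x$total_deaths_averted, x$total_admissions_averted))
  cat(sprintf("  QALYs gained (disc.) %.2f, health-care cost change %.0f\n",
              x$total_qalys, x$total_cost_change))
  invisible(x)
}
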