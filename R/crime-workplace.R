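# Crime, workplace absence and unemployment channels -------------------------

#' Default synthetic crime catalogue
#'
#' Twenty crime classifications grouped into six broad groups (violent
#' disorder, wounding, assault without injury, vehicle-related theft,
#' burglary/robbery/theft, criminal damage), each with a synthetic baseline
#' annual reported volume, an under-reporting multiplier, a unit cost, a
#' victim quality-of-life loss per offence and a target attributable
#' fraction used to calibrate the peak-basis risk functions.
#'
#' @return Data frame with one row per crime classification.
#' @export
default_crime_catalogue <- function() {
  groups <- c(rep("violent_disorder", 3), rep("wounding", 4),
              rep("assault_no_injury", 3), rep("vehicle_theft", 3),
              rep("burglary_robbery_theft", 4), rep("criminal_damage", 3))
  n <- length(groups)
  data.frame(
    category_id = sprintf("%s_%d", groups, stats::ave(seq_len(n), groups,
                                                      FUN = seq_along)),
    broad_group = groups,
    baseline_volume = round(c(40, 25, 15, 60, 35, 20, 12, 80, 50, 30,
                              45, 30, 20, 55, 40, 30, 22, 70, 45, 28) * 1e3),
    multiplier = c(rep(1.7, 3), c(1.9, 1.9, 1.9, 1.9), rep(2.1, 3),
                   rep(1.2, 3), rep(1.35, 4), rep(1.5, 3)),
    unit_cost = c(rep(9000, 3), rep(8000, 4), rep(1500, 3), rep(900, 3),
                  rep(1800, 4), rep(700, 3)),
    victim_qaly_loss = c(rep(0.012, 3), rep(0.018, 4), rep(0.004, 3),
                         rep(0.0008, 3), rep(0.002, 4), rep(0.0006, 3)),
    target_aaf = c(rep(0.45, 3), rep(0.37, 4), rep(0.30, 3), rep(0.10, 3),
                   rep(0.15, 4), rep(0.22, 3)),
    stringsAsFactors = FALSE)
}

#' Default offender apportionment weights
#'
#' Shares of each crime category's offences attributed to offender sex x
#' age-band cells, built from stated assumptions: offences skew male and
#' young; the 16-17 and 18-24 bands split the original youth band with
#' equal per-year probabilities; rates decline linearly with age above 35.
#' Weights sum to 1 within each category.
#'
#' @param categories A [default_crime_catalogue()] data frame.
#' @return Data frame: category_id, sex, age_band, weight.
#' @export
default_offender_weights <- function(categories = default_crime_catalogue()) {
  bands <- age_bands()
  # per-year offending propensity by band midpoint, linear decline over 35
  base <- c("11-15" = 0.5, "16-17" = 1.0, "18-24" = 1.0, "25-34" = 0.8,
            "35-44" = 0.5, "45-54" = 0.3, "55-64" = 0.15, "65-74" = 0.05,
            "75+" = 0.02)
  yrs <- c("11-15" = 5, "16-17" = 2, "18-24" = 7, "25-34" = 10,
           "35-44" = 10, "45-54" = 10, "55-64" = 10, "65-74" = 10,
           "75+" = 10)
  cell <- expand.grid(sex = sexes(), age_band = bands,
                      stringsAsFactors = FALSE)
  w <- base[cell$age_band] * yrs[cell$age_band] *
    ifelse(cell$sex == "male", 0.8, 0.2)
  w <- w / sum(w)
  out <- do.call(rbind, lapply(categories$category_id, function(cid)
    data.frame(category_id = cid, sex = cell$sex, age_band = cell$age_band,
               weight = w, stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}

# risk-function age group used for crime/absence: under-16, 16-25; over 25
# reuses the 16-25 functions (their estimation source covers only those).
crime_age_group <- function(age_band) {
  ifelse(age_band == "11-15", "under16", "16-25")
}

#' Calibrate crime risk functions
#'
#' Peak-day-basis two-part linear relative-risk functions per sex x age
#' group (under-16 and 16-25; older bands reuse the 16-25 function),
#' calibrated per crime category to its target attributable fraction on the
#' 16-25 population (the apportionment weights carry the age profile).
#'
#' @param individuals Output of [assign_subgroups()].
#' @param categories A [default_crime_catalogue()] data frame.
#' @param thresholds Acute peak thresholds by sex.
#' @return Named list of `risk_function`s keyed `category_id|sex|age_group`.
#' @export
calibrate_crime_risk_functions <- function(
    individuals, categories = default_crime_catalogue(),
    thresholds = default_risk_thresholds()$acute_peak) {
  out <- list()
  grp <- crime_age_group(individuals$age_band)
  for (g in c("under16", "16-25")) for (s in sexes()) {
    sel <- grp == g & individuals$sex == s
    if (!any(sel)) next
    peak <- individuals$peak_day_units[sel]
    w <- individuals$weight[sel]
    th <- thresholds[[s]]
    for (i in seq_len(nrow(categories))) {
      template <- risk_function(categories$category_id[i], "peak_day",
                                "partially", "acute", sex = s,
                                age_group = g)
      rf <- if (sum(w * pmax(peak - th, 0)) > 0)
        fit_two_part_slope(peak, w, th, categories$target_aaf[i], template)
      else { template$threshold <- th; template }
      out[[paste(categories$category_id[i], s, g, sep = "|")]] <- rf
    }
  }
  out
}

#' Crime volume changes from a consumption change
#'
#' Per category and offender subgroup: the baseline volume (scaled by the
#' under-reporting multiplier) apportioned to the subgroup is reduced by
#' the subgroup's PIF computed on peak-day consumption through the
#' category's calibrated risk function (over-25 bands reuse the 16-25
#' function).  Subgroup changes sum exactly to the category total.
#'
#' @param before,after Individuals tables (aligned rows; peak_day_units
#'   differ).
#' @param crime_rfs Output of [calibrate_crime_risk_functions()].
#' @param categories A [default_crime_catalogue()] data frame.
#' @param offender_weights A [default_offender_weights()] data frame.
#' @return List: `by_subgroup` (category x sex x age_band changes, signed,
#'   negative = offences averted), `by_category` (totals with cost and
#'   victim-QALY valuations aggregated later).
#' @export
crime_pif_and_volumes <- function(before, after, crime_rfs,
                                  categories = default_crime_catalogue(),
                                  offender_weights =
                                    default_offender_weights()) {
  stopifnot(identical(before$person_id, after$person_id))
  ow <- offender_weights
  miss <- setdiff(categories$category_id, unique(ow$category_id))
  if (length(miss))
    stop("offender weights missing for: ", paste(miss, collapse = ", "),
         call. = FALSE)
  # PIF per sex x age band (risk-function group mapping inside)
  cells <- expand.grid(sex = sexes(), age_band = age_bands(),
                       stringsAsFactors = FALSE)
  res <- vector("list", nrow(cells) * nrow(categories))
  k <- 0
  for (ci in seq_len(nrow(cells))) {
    s <- cells$sex[ci]; band <- cells$age_band[ci]
    g <- crime_age_group(band)
    sel <- before$sex == s & before$age_band == band
    for (i in seq_len(nrow(categories))) {
      cid <- categories$category_id[i]
      key <- paste(cid, s, band, sep = "|")
      rf <- crime_rfs[[paste(cid, s, g, sep = "|")]]
      pif <- if (is.null(rf) || !any(sel)) 0 else
        potential_impact_fraction(rf, before$peak_day_units[sel],
                                  after$peak_day_units[sel],
                                  before$weight[sel])
      wgt <- ow$weight[ow$category_id == cid & ow$sex == s &
                         ow$age_band == band]
      wgt <- if (length(wgt)) wgt[1] else 0
      base <- categories$baseline_volume[i] * categories$multiplier[i] * wgt
      k <- k + 1
      res[[k]] <- data.frame(category_id = cid, sex = s, age_band = band,
                             baseline = base, pif = pif,
                             change = -base * pif,
                             stringsAsFactors = FALSE)
    }
  }
  by_sub <- do.call(rbind, res)
  agg <- stats::aggregate(cbind(baseline, change) ~ category_id, by_sub, sum)
  agg <- merge(agg, categories[, c("category_id", "unit_cost",
                                   "victim_qaly_loss")], by = "category_id")
  agg$cost_change <- agg$change * agg$unit_cost
  agg$victim_qalys_gained <- -agg$change * agg$victim_qaly_loss
  list(by_subgroup = by_sub, by_category = agg,
       total_offence_change = sum(by_sub$change),
       total_cost_change = sum(agg$cost_change),
       total_victim_qalys = sum(agg$victim_qalys_gained))
}

#' Default workplace parameters
#'
#' Unemployment calibration target (problem drinkers' probability of being
#' in work reduced by 6.9 %), harmful-drinking mean-basis thresholds of 7.1
#' units/day (men) and 5 units/day (women), and synthetic baseline absence
#' days, unemployment counts, salaries and participation rates per sex x
#' age band for the working-age bands.
#'
#' @return List of class `workplace_params`.
#' @export
default_workplace_params <- function() {
  working <- c("16-17", "18-24", "25-34", "35-44", "45-54", "55-64")
  cell <- expand.grid(sex = sexes(), age_band = working,
                      stringsAsFactors = FALSE)
  cell$participation <- ifelse(cell$sex == "male", 0.82, 0.72) *
    ifelse(cell$age_band %in% c("16-17", "55-64"), 0.6, 1)
  cell$salary <- c("16-17" = 9000, "18-24" = 17000, "25-34" = 24000,
                   "35-44" = 27000, "45-54" = 27500,
                   "55-64" = 25000)[cell$age_band] *
    ifelse(cell$sex == "male", 1.1, 0.9)
  cell$baseline_absence_days <- 400000 * cell$participation
  cell$baseline_unemployed <- 30000 * ifelse(cell$sex == "male", 1.15, 0.85)
  structure(list(work_reduction_target = 0.069,
                 thresholds_weekly =
                   default_risk_thresholds()$unemployment_weekly,
                 absence_aaf = 0.05,
                 cells = cell, working_bands = working),
            class = "workplace_params")
}

#' Calibrate the unemployment risk function
#'
#' A mean-weekly-basis two-part linear function with thresholds at the
#' harmful-drinking boundary (7.1 units/day men, 5 units/day women, x7 on
#' the weekly basis), calibrated per sex so that the implied
#' work-probability reduction over the harmful working-age drinkers equals
#' the target (6.9 %).  The implied reduction is measured as the implied
#' attributable fraction (excess-over-total) of the function over that
#' subpopulation, which makes the calibration round trip exact; for women
#' the target is first adjusted by the female/male participation-rate ratio
#' to reflect differential workforce participation.  By construction the
#' function returns RR = 1 for moderate and hazardous drinkers, so
#' unemployment effects are exactly zero outside the harmful group, and no
#' time lag applies.
#'
#' @param individuals Output of [assign_subgroups()].
#' @param params A [default_workplace_params()] list.
#' @return Named list of `risk_function`s by sex, with the achieved
#'   reduction attached as attribute `implied_reduction`.
#' @export
calibrate_unemployment <- function(individuals,
                                   params = default_workplace_params()) {
  out <- list()
  part <- stats::aggregate(participation ~ sex, params$cells, mean)
  ratio <- part$participation[part$sex == "female"] /
    part$participation[part$sex == "male"]
  for (s in sexes()) {
    th <- params$thresholds_weekly[[s]]
    target <- params$work_reduction_target * if (s == "female") ratio else 1
    sel <- individuals$sex == s &
      individuals$age_band %in% params$working_bands &
      individuals$drinker_level == "harmful"
    if (!any(sel)) {
      if (target > 0)
        stop("no harmful drinkers of working age (", s,
             "): calibration infeasible", call. = FALSE)
      next
    }
    cons <- individuals$mean_weekly_units[sel]
    w <- individuals$weight[sel]
    template <- risk_function("unemployment", "mean_weekly", "partially",
                              "acute", sex = s)
    rf <- fit_two_part_slope(cons, w, th, target, template)
    attr(rf, "implied_reduction") <- implied_aaf(rf, cons, w)
    out[[s]] <- rf
  }
  out
}

#' Implied work-probability reduction of an unemployment function
#'
#' Re-evaluates the calibrated function over the harmful working-age
#' drinkers of the given sex and returns the implied attributable fraction.
#'
#' @param rf Calibrated unemployment `risk_function`.
#' @param individuals Output of [assign_subgroups()].
#' @param params A [default_workplace_params()] list.
#' @return Fraction in [0, 1).
#' @export
implied_work_reduction <- function(rf, individuals,
                                   params = default_workplace_params()) {
  sel <- individuals$sex == rf$sex &
    individuals$age_band %in% params$working_bands &
    individuals$drinker_level == "harmful"
  implied_aaf(rf, individuals$mean_weekly_units[sel],
              individuals$weight[sel])
}

#' Unemployment change from a consumption change
#'
#' Per sex and age band: `change = baseline_unemployed * PIF` through the
#' calibrated unemployment function on mean weekly consumption of the
#' harmful drinkers (others contribute RR = 1 and, being excluded from the
#' calibration scope, zero effect), valued at the cell's average salary.
#' Negative change = unemployment averted.
#'
#' @param before,after Individuals tables (aligned; mean_weekly_units
#'   differ; drinker_level at baseline).
#' @param unemployment_rfs Output of [calibrate_unemployment()].
#' @param params A [default_workplace_params()] list.
#' @return Data frame per sex x age band with persons and cost change, plus
#'   totals as attributes.
#' @export
unemployment_change <- function(before, after, unemployment_rfs,
                                params = default_workplace_params()) {
  stopifnot(identical(before$person_id, after$person_id))
  cells <- params$cells
  cells$persons_change <- 0
  for (i in seq_len(nrow(cells))) {
    s <- cells$sex[i]; band <- cells$age_band[i]
    rf <- unemployment_rfs[[s]]
    if (is.null(rf)) next
    sel <- before$sex == s & before$age_band == band &
      before$drinker_level == "harmful"
    if (!any(sel)) next
    pif <- potential_impact_fraction(rf, before$mean_weekly_units[sel],
                                     after$mean_weekly_units[sel],
                                     before$weight[sel])
    cells$persons_change[i] <- -cells$baseline_unemployed[i] * pif
  }
  cells$cost_change <- cells$persons_change * cells$salary
  attr(cells, "total_persons") <- sum(cells$persons_change)
  attr(cells, "total_cost") <- sum(cells$cost_change)
  cells
}

#' Calibrate workplace-absence risk functions
#'
#' Peak-day-basis two-part functions per sex x age group (same age grouping
#' as crime), calibrated to the configured absence attributable fraction.
#' Thresholds default to the acute thresholds (4/3 units), as no dedicated
#' absence threshold is defined.
#'
#' @inheritParams calibrate_crime_risk_functions
#' @param params A [default_workplace_params()] list.
#' @return Named list of `risk_function`s keyed `sex|age_group`.
#' @export
calibrate_absence_risk_functions <- function(
    individuals, params = default_workplace_params(),
    thresholds = default_risk_thresholds()$acute_peak) {
  out <- list()
  grp <- crime_age_group(individuals$age_band)
  for (g in c("under16", "16-25")) for (s in sexes()) {
    sel <- grp == g & individuals$sex == s
    if (!any(sel)) next
    peak <- individuals$peak_day_units[sel]
    w <- individuals$weight[sel]
    th <- thresholds[[s]]
    template <- risk_function("absence", "peak_day", "partially", "acute",
                              sex = s, age_group = g)
    rf <- if (sum(w * pmax(peak - th, 0)) > 0)
      fit_two_part_slope(peak, w, th, params$absence_aaf, template)
    else { template$threshold <- th; template }
    out[[paste(s, g, sep = "|")]] <- rf
  }
  out
}

#' Workplace absence change from a consumption change
#'
#' Per working-age sex x age band: revised absent days are
#' `baseline * (1 - PIF)` on peak-day consumption; the change is valued at
#' the cell salary converted to a day rate (salary / 220 working days).
#' Non-working-age bands contribute zero.
#'
#' @param before,after Individuals tables (aligned).
#' @param absence_rfs Output of [calibrate_absence_risk_functions()].
#' @param params A [default_workplace_params()] list.
#' @return Data frame per sex x age band with days and cost change, totals
#'   as attributes.
#' @export
absence_change <- function(before, after, absence_rfs,
                           params = default_workplace_params()) {
  stopifnot(identical(before$person_id, after$person_id))
  cells <- params$cells
  cells$days_change <- 0
  for (i in seq_len(nrow(cells))) {
    s <- cells$sex[i]; band <- cells$age_band[i]
    rf <- absence_rfs[[paste(s, crime_age_group(band), sep = "|")]]
    if (is.null(rf)) next
    sel <- before$sex == s & before$age_band == band
    if (!any(sel)) next
    pif <- potential_impact_fraction(rf, before$peak_day_units[sel],
                                     after$peak_day_units[sel],
                                     before$weight[sel])
    cells$days_change[i] <- -cells$baseline_absence_days[i] * pif
  }
  cells$cost_change <- cells$days_change * cells$salary / 220
  attr(cells, "total_days") <- sum(cells$days_change)
  attr(cells, "total_cost") <- sum(cells$cost_change)
  cells
}
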