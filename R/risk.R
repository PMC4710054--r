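# Relative-risk functions, AAF arithmetic and the potential impact fraction --
#
# Two functional forms are supported.  Published-curve functions carry a
# tabulated relative-risk-by-consumption curve (monotone linear
# interpolation between the tabulated points, constant beyond the ends).
# Two-part linear functions are flat at RR = 1 up to a threshold and rise
# linearly above it; their slope is calibrated either to a target
# attributable fraction or to an observed annual volume of incidents.

#' Default risk-function thresholds (units on the basis scale)
#'
#' Acute harms: risk starts rising above a peak-day intake of 4 units (men)
#' / 3 units (women).  Chronic wholly attributable harms: 3 units/day (men)
#' / 2 units/day (women), converted to the mean-weekly basis by x7.
#' Unemployment: mean intake of 7.1 units/day (men) / 5 units/day (women),
#' i.e. the harmful-drinking boundary, again x7 on the weekly basis.
#'
#' @return Nested list of thresholds by harm class and sex.
#' @export
default_risk_thresholds <- function() {
  list(acute_peak = c(male = 4, female = 3),
       chronic_wholly_weekly = c(male = 3 * 7, female = 2 * 7),
       unemployment_weekly = c(male = 7.1 * 7, female = 5 * 7))
}

#' Construct a relative-risk function
#'
#' @param condition_id Identifier of the condition/harm.
#' @param basis `"mean_weekly"` or `"peak_day"` (units of the consumption
#'   argument).
#' @param attribution `"wholly"` or `"partially"`.
#' @param timing `"chronic"` or `"acute"`.
#' @param form `"two_part_linear"` or `"published_curve"`.
#' @param threshold Units on the basis scale below which RR = 1 (two-part
#'   form).
#' @param slope RR increase per unit above the threshold (two-part form).
#' @param curve Data frame with `units`, `rr` columns (published form).
#' @param sex Sex the function applies to (`"male"`, `"female"` or
#'   `"both"`).
#' @param age_group Optional age-applicability label.
#' @return Object of class `risk_function`.
#' @export
risk_function <- function(condition_id, basis, attribution, timing,
                          form = "two_part_linear", threshold = 0,
                          slope = 0, curve = NULL, sex = "both",
                          age_group = NULL) {
  stopifnot(basis %in% c("mean_weekly", "peak_day"),
            attribution %in% c("wholly", "partially"),
            timing %in% c("chronic", "acute"),
            form %in% c("two_part_linear", "published_curve"),
            threshold >= 0, slope >= 0)
  if (form == "published_curve") {
    if (is.null(curve) || is.unsorted(curve$units, strictly = TRUE) ||
        any(curve$rr < 0))
      stop("published_curve requires a curve with strictly increasing ",
           "units and non-negative rr", call. = FALSE)
  }
  structure(list(condition_id = condition_id, basis = basis,
                 attribution = attribution, timing = timing, form = form,
                 threshold = threshold, slope = slope, curve = curve,
                 sex = sex, age_group = age_group),
            class = "risk_function")
}

#' @export
print.risk_function <- function(x, ...) {
  cat(sprintf("<risk_function> %s [%s, %s %s, %s]\n", x$condition_id,
              x$basis, x$timing, x$attribution, x$sex))
  if (x$form == "two_part_linear")
    cat(sprintf("  two-part linear: RR = 1 below %g units, slope %g/unit\n",
                x$threshold, x$slope))
  else
    cat(sprintf("  published curve: %d tabulated points, RR up to %g\n",
                nrow(x$curve), max(x$curve$rr)))
  invisible(x)
}

#' Evaluate a relative-risk function
#'
#' Two-part form: RR = 1 for consumption at or below the threshold,
#' 1 + slope * (c - threshold) above it.  Published form: linear
#' interpolation between the tabulated points, constant beyond either end.
#'
#' @param rf A [risk_function()].
#' @param consumption Non-negative numeric vector on the function's basis
#'   scale (units).
#' @return Numeric vector of relative risks (>= 0).
#' @export
evaluate_rr <- function(rf, consumption) {
  if (any(consumption < 0))
    stop("consumption must be non-negative", call. = FALSE)
  if (rf$form == "two_part_linear") {
    1 + rf$slope * pmax(consumption - rf$threshold, 0)
  } else {
    stats::approx(rf$curve$units, rf$curve$rr, xout = consumption,
                  rule = 2, ties = "ordered")$y
  }
}

#' Implied attributable fraction of a risk function over a population
#'
#' The excess-over-total form: `AAF = sum(w * (RR - 1)) / sum(w * RR)`,
#' which is exactly the potential impact fraction of the zero-consumption
#' counterfactual (the identity the model uses for validation).  Equals 0
#' when every RR is 1 and approaches 1 as risk grows without bound.
#'
#' @param rf A [risk_function()].
#' @param consumption Numeric vector on the basis scale.
#' @param weights Non-negative sample weights (same length).
#' @return A fraction in [0, 1).
#' @export
implied_aaf <- function(rf, consumption, weights) {
  stopifnot(length(consumption) == length(weights), all(weights >= 0))
  if (length(consumption) == 0 || sum(weights) <= 0)
    stop("implied_aaf needs a population with positive total weight",
         call. = FALSE)
  rr <- evaluate_rr(rf, consumption)
  sum(weights * (rr - 1)) / sum(weights * rr)
}

#' Calibrate the slope of a two-part linear risk function to a target AAF
#'
#' For the two-part form, the implied AAF as a function of the slope s is
#' `s E / (W + s E)` with `E = sum(w * max(c - T, 0))` and `W = sum(w)`:
#' strictly increasing in s whenever consumption mass exists above the
#' threshold, with the unique exact solution
#' `s = AAF W / ((1 - AAF) E)`.  The fitted function reproduces the target
#' AAF to machine precision.
#'
#' @param consumption,weights Population on the function's basis scale.
#' @param threshold Threshold T (units).
#' @param target_aaf Target attributable fraction in [0, 1).
#' @param template Optional [risk_function()] supplying metadata for the
#'   returned object.
#' @return A calibrated `risk_function` (two-part linear).
#' @export
fit_two_part_slope <- function(consumption, weights, threshold, target_aaf,
                               template = NULL) {
  stopifnot(target_aaf >= 0, target_aaf < 1)
  W <- sum(weights)
  E <- sum(weights * pmax(consumption - threshold, 0))
  if (target_aaf == 0) {
    slope <- 0
  } else if (E <= 0) {
    stop("no consumption mass above the threshold: target AAF ", target_aaf,
         " is infeasible", call. = FALSE)
  } else {
    slope <- target_aaf * W / ((1 - target_aaf) * E)
  }
  if (is.null(template))
    template <- risk_function("calibrated", "mean_weekly", "partially",
                              "chronic")
  template$form <- "two_part_linear"
  template$threshold <- threshold
  template$slope <- slope
  template$curve <- NULL
  template
}

#' Calibrate an absolute two-part risk function to an observed incident
#' volume
#'
#' For wholly attributable harms the absolute risk is
#' `r(c) = s * max(c - T, 0)` (zero below the threshold).  The slope is
#' fitted so that the expected annual incidents over the weighted
#' population, `s * sum(w * max(c - T, 0))`, equal the observed volume.
#'
#' @param consumption,weights Population on the basis scale.
#' @param threshold Threshold T (units).
#' @param observed_incidents Observed annual incident volume (>= 0).
#' @param template Optional [risk_function()] metadata template.
#' @return A list: `rf` (the calibrated relative-form function, slope in RR
#'   units per consumption unit), `absolute_slope` (incidents per
#'   person-year per unit above threshold) and `expected_incidents`.
#' @export
fit_slope_to_incidence <- function(consumption, weights, threshold,
                                   observed_incidents, template = NULL) {
  stopifnot(observed_incidents >= 0, all(weights >= 0))
  E <- sum(weights * pmax(consumption - threshold, 0))
  if (observed_incidents == 0) {
    s <- 0
  } else if (E <= 0) {
    stop("no consumption mass above the threshold: observed incidents ",
         "cannot be attributed", call. = FALSE)
  } else {
    s <- observed_incidents / E
  }
  if (is.null(template))
    template <- risk_function("calibrated", "peak_day", "wholly", "acute")
  template$form <- "two_part_linear"
  template$threshold <- threshold
  template$slope <- s
  template$curve <- NULL
  list(rf = template, absolute_slope = s,
       expected_incidents = s * E)
}

#' Potential impact fraction
#'
#' `PIF = 1 - sum(w * RR_after) / sum(w * RR_before)` over the same
#' weighted individuals in both consumption states.  Positive when risk
#' falls; the revised absolute harm rate is `baseline * (1 - PIF)`.  With
#' the after-state consumption all zero the PIF equals the implied AAF of
#' the before state.
#'
#' @param rf A [risk_function()].
#' @param before,after Numeric consumption vectors on the basis scale, one
#'   entry per individual, aligned.
#' @param weights Sample weights, aligned with both states.
#' @return The PIF (a real number, at most 1).
#' @export
potential_impact_fraction <- function(rf, before, after, weights) {
  if (length(before) != length(after) ||
      length(before) != length(weights))
    stop("before/after states must cover the same weighted individuals",
         call. = FALSE)
  rr0 <- evaluate_rr(rf, before)
  rr1 <- evaluate_rr(rf, after)
  1 - sum(weights * rr1) / sum(weights * rr0)
}

#' Calibrate the full risk-function catalogue on a baseline population
#'
#' For each condition in the harm configuration and each sex x age band
#' cell: partially attributable two-part conditions are calibrated to the
#' cell's target AAF; wholly attributable conditions are calibrated to the
#' cell's observed incident volume (baseline mortality rate x cell weight);
#' published-curve conditions take their tabulated curve as supplied.
#' Thresholds follow [default_risk_thresholds()] by timing/attribution and
#' sex.
#'
#' @param individuals Output of [assign_subgroups()].
#' @param harm_config A [default_harm_config()]-shaped list.
#' @return Named list (by `condition_id|sex|age_band`) of `risk_function`s.
#' @export
calibrate_risk_functions <- function(individuals,
                                     harm_config = default_harm_config()) {
  thr <- default_risk_thresholds()
  rates <- generate_baseline_harms(harm_config)
  conds <- harm_config$conditions
  out <- list()
  for (i in seq_len(nrow(rates))) {
    row <- rates[i, ]
    cn <- conds[conds$condition_id == row$condition_id, ]
    sel <- individuals$sex == row$sex & individuals$age_band == row$age_band
    if (!any(sel)) next
    cons <- if (cn$basis == "mean_weekly")
      individuals$mean_weekly_units[sel] else individuals$peak_day_units[sel]
    w <- individuals$weight[sel]
    th <- if (cn$timing == "acute") thr$acute_peak[[row$sex]]
          else thr$chronic_wholly_weekly[[row$sex]]
    template <- risk_function(row$condition_id, cn$basis, cn$attribution,
                              cn$timing, sex = row$sex,
                              age_group = row$age_band)
    rf <- if (cn$form == "published_curve") {
      template$form <- "published_curve"
      template$curve <- harm_config$curves[[row$condition_id]]
      template
    } else if (cn$attribution == "partially") {
      target <- row$aaf
      if (sum(w * pmax(cons - th, 0)) <= 0) {
        template$threshold <- th   # no at-risk mass: flat function
        template
      } else fit_two_part_slope(cons, w, th, target, template)
    } else {
      observed <- row$mortality_rate * sum(w)
      if (sum(w * pmax(cons - th, 0)) <= 0) {
        template$threshold <- th
        template
      } else fit_slope_to_incidence(cons, w, th, observed, template)$rf
    }
    out[[paste(row$condition_id, row$sex, row$age_band, sep = "|")]] <- rf
  }
  out
}
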