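# Population subgroups and drinker classification ---------------------------

#' Modelled age bands
#'
#' The nine age bands used throughout the model, as fixed strings (half-open
#' on age in completed years).  Using fixed labels rather than numeric cut
#' points avoids off-by-one drift between data sets.
#'
#' @return Character vector of length 9.
#' @export
age_bands <- function() {
  c("11-15", "16-17", "18-24", "25-34", "35-44",
    "45-54", "55-64", "65-74", "75+")
}

#' Drinker levels
#'
#' @return Character vector: moderate, hazardous, harmful.
#' @export
drinker_levels <- function() c("moderate", "hazardous", "harmful")

#' Sexes
#' @return Character vector: male, female.
#' @export
sexes <- function() c("male", "female")

#' The 16 beverage categories
#'
#' Beer, wine, spirits and ready-to-drinks (RTDs), each split by sector
#' (on-trade vs off-trade) and price tier (low vs high priced), giving the
#' 16 demand categories the elasticity matrices are indexed by.
#'
#' @return Character vector of length 16.
#' @export
beverage_categories <- function() {
  bev <- c("beer", "wine", "spirit", "rtd")
  out <- as.vector(outer(bev, c("on", "off"), function(b, s)
    paste(b, s, sep = "_")))
  as.vector(outer(out, c("low", "high"), paste, sep = "_"))
}

#' Consumption thresholds
#'
#' Default classification thresholds, in grams of ethanol (1 UK unit = 8 g):
#' moderate drinking is at or below 168 g/week (men) and 112 g/week (women);
#' harmful drinking is above 400 g/week (men) and 280 g/week (women);
#' binge drinking is a peak-day intake strictly above 64 g (men) or 48 g
#' (women), i.e. more than twice the recommended daily limit.
#'
#' @param moderate_max Named vector (male, female), grams/week.
#' @param harmful_min Named vector (male, female), grams/week.
#' @param binge_min Named vector (male, female), grams/day.
#' @param grams_per_unit Grams of ethanol per UK unit.
#' @return An object of class `thresholds`.
#' @export
default_thresholds <- function(moderate_max = c(male = 168, female = 112),
                               harmful_min = c(male = 400, female = 280),
                               binge_min = c(male = 64, female = 48),
                               grams_per_unit = 8) {
  stopifnot(all(moderate_max > 0), all(harmful_min > 0), all(binge_min > 0),
            grams_per_unit > 0,
            all(moderate_max[sexes()] < harmful_min[sexes()]))
  structure(list(moderate_max = moderate_max, harmful_min = harmful_min,
                 binge_min = binge_min, grams_per_unit = grams_per_unit),
            class = "thresholds")
}

#' @export
print.thresholds <- function(x, ...) {
  cat("Drinker classification thresholds (grams of ethanol):\n")
  cat(sprintf("  moderate <= %g (M) / %g (F) g/week\n",
              x$moderate_max["male"], x$moderate_max["female"]))
  cat(sprintf("  harmful  >  %g (M) / %g (F) g/week\n",
              x$harmful_min["male"], x$harmful_min["female"]))
  cat(sprintf("  binge    >  %g (M) / %g (F) g/peak day\n",
              x$binge_min["male"], x$binge_min["female"]))
  invisible(x)
}

check_sex <- function(sex) {
  if (!all(sex %in% sexes()))
    stop("sex must be 'male' or 'female'", call. = FALSE)
}

#' Classify mean weekly consumption into a drinker level
#'
#' Moderate at or below the recommended weekly limit, harmful strictly above
#' the harmful threshold, hazardous in between.  Consumption exactly at the
#' harmful threshold (400/280 g/week) is classified hazardous: the hazardous
#' band is treated as closed at its upper bound, since neither band is open
#' or closed there by definition.  Abstainers (zero consumption) fall in the
#' moderate group.
#'
#' @param sex "male"/"female", recycled against consumption.
#' @param mean_weekly_grams Non-negative mean weekly consumption, grams.
#' @param thresholds A [default_thresholds()] object.
#' @return Character vector of drinker levels.
#' @export
classify_drinker <- function(sex, mean_weekly_grams,
                             thresholds = default_thresholds()) {
  check_sex(sex)
  if (any(mean_weekly_grams < 0))
    stop("mean_weekly_grams must be non-negative", call. = FALSE)
  n <- max(length(sex), length(mean_weekly_grams))
  sex <- rep_len(sex, n)
  g <- rep_len(mean_weekly_grams, n)
  mod <- unname(thresholds$moderate_max[sex])
  harm <- unname(thresholds$harmful_min[sex])
  ifelse(g <= mod, "moderate", ifelse(g > harm, "harmful", "hazardous"))
}

#' Classify peak-day consumption as binge drinking
#'
#' TRUE iff peak-day grams strictly exceed the binge threshold for the sex
#' (64 g men, 48 g women).  The same thresholds are applied to the 11-15
#' band as to adults; no age-specific limit is defined.
#'
#' @inheritParams classify_drinker
#' @param peak_day_grams Non-negative peak single-day consumption, grams.
#' @return Logical vector.
#' @export
classify_binge <- function(sex, peak_day_grams,
                           thresholds = default_thresholds()) {
  check_sex(sex)
  if (any(peak_day_grams < 0))
    stop("peak_day_grams must be non-negative", call. = FALSE)
  n <- max(length(sex), length(peak_day_grams))
  unname(rep_len(peak_day_grams, n) >
           thresholds$binge_min[rep_len(sex, n)])
}

#' All 54 subgroup keys
#'
#' @return Data frame of the 54 sex x age band x drinker level combinations,
#'   with a `subgroup` label column.
#' @export
subgroup_keys <- function() {
  g <- expand.grid(drinker_level = drinker_levels(), age_band = age_bands(),
                   sex = sexes(), stringsAsFactors = FALSE,
                   KEEP.OUT.ATTRS = FALSE)
  g <- g[, c("sex", "age_band", "drinker_level")]
  g$subgroup <- paste(g$sex, g$age_band, g$drinker_level, sep = "|")
  g
}

#' Assign individuals to modelled subgroups
#'
#' Deterministically partitions a consumption microdata table into the 54
#' sex x age band x drinker-level subgroups.  Classification uses mean weekly
#' units converted to grams; the partition conserves total weight exactly.
#'
#' @param individuals Data frame with columns `person_id`, `sex`, `age_band`,
#'   `weight`, `mean_weekly_units` (and any others, which are ignored).
#' @param thresholds A [default_thresholds()] object.
#' @return `individuals` with `drinker_level` and `subgroup` columns added.
#' @export
assign_subgroups <- function(individuals, thresholds = default_thresholds()) {
  if (nrow(individuals) == 0) {
    individuals$drinker_level <- character(0)
    individuals$subgroup <- character(0)
    return(individuals)
  }
  check_sex(individuals$sex)
  bad <- setdiff(unique(individuals$age_band), age_bands())
  if (length(bad))
    stop("unknown age band(s): ", paste(bad, collapse = ", "), call. = FALSE)
  if (any(individuals$weight < 0))
    stop("weights must be non-negative", call. = FALSE)
  grams <- individuals$mean_weekly_units * thresholds$grams_per_unit
  individuals$drinker_level <-
    classify_drinker(individuals$sex, grams, thresholds)
  individuals$subgroup <- paste(individuals$sex, individuals$age_band,
                                individuals$drinker_level, sep = "|")
  individuals
}

#' Summarise weight and consumption by subgroup
#'
#' @param individuals Output of [assign_subgroups()].
#' @return Data frame with one row per occupied subgroup: total weight,
#'   weighted mean weekly units and person count.
#' @export
subgroup_summary <- function(individuals) {
  if (nrow(individuals) == 0)
    return(data.frame(subgroup = character(0), weight = numeric(0),
                      mean_weekly_units = numeric(0), n = integer(0)))
  w <- tapply(individuals$weight, individuals$subgroup, sum)
  wu <- tapply(individuals$weight * individuals$mean_weekly_units,
               individuals$subgroup, sum)
  n <- tapply(individuals$weight, individuals$subgroup, length)
  data.frame(subgroup = names(w), weight = as.numeric(w),
             mean_weekly_units = as.numeric(wu) / pmax(as.numeric(w), 1e-300),
             n = as.integer(n), row.names = NULL)
}

#' Read / write consumption microdata
#'
#' Plain CSV with a fixed documented header: person_id, sex, age_band,
#' weight, mean_weekly_units, peak_day_units and sixteen `share_<category>`
#' columns holding the beverage mix.  Units are UK units (8 g ethanol).
#'
#' @param path File path.
#' @return For `read_microdata`, a data frame of individuals.
#' @export
read_microdata <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("person_id", "sex", "age_band", "weight",
            "mean_weekly_units", "peak_day_units",
            paste0("share_", beverage_categories()))
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("microdata missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  x
}

#' @rdname read_microdata
#' @param individuals Data frame of individuals.
#' @export
write_microdata <- function(individuals, path) {
  utils::write.csv(individuals, path, row.names = FALSE)
  invisible(path)
}

# share matrix helper: n x 16 matrix of beverage shares
share_matrix <- function(individuals) {
  cols <- paste0("share_", beverage_categories())
  m <- as.matrix(individuals[, cols, drop = FALSE])
  colnames(m) <- beverage_categories()
  m
}
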