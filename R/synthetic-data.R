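# Seeded synthetic-data generators -------------------------------------------
#
# Stand-ins for the survey microdata the model consumes: a cross-sectional
# consumption survey (weighted individuals, mean weekly + peak day units,
# beverage mix) and a purchasing diary (weighted transactions with usual and
# sold prices per unit).  Generators are deterministic for a fixed seed.

#' Default synthetic population configuration
#'
#' Describes a survey-like population: counts per sex x age band, abstainer
#' fractions, a right-skewed (log-normal) mean-weekly-consumption family per
#' cell, linear peak-from-mean ("binge") coefficients per sex x age band x
#' drinker level, and beverage-preference weights over the 16 categories.
#' The log-normal family is a modelling convenience: the real survey is an
#' empirical non-parametric sample, so the only contract here is right skew
#' with configurable location/scale.
#'
#' @param n_per_cell Individuals sampled per sex x age band cell.
#' @param seed Integer seed; every generated table is reproducible given it.
#' @return A list of class `population_config`.
#' @export
default_population_config <- function(n_per_cell = 200, seed = 42) {
  bands <- age_bands()
  cells <- expand.grid(sex = sexes(), age_band = bands,
                       stringsAsFactors = FALSE)
  # location of weekly units by age: rises into mid-life, falls in old age
  shape <- c(0.25, 0.6, 1.15, 1.2, 1.1, 1.0, 0.85, 0.6, 0.45)
  names(shape) <- bands
  base_mean <- c(male = 14, female = 8)   # median weekly units, 25-34 cell
  cells$meanlog <- log(base_mean[cells$sex] * shape[cells$age_band] /
                         shape["25-34"])
  cells$sdlog <- ifelse(cells$age_band %in% c("11-15", "16-17"), 1.1, 0.95)
  abst <- c("11-15" = 0.55, "16-17" = 0.25, "18-24" = 0.12, "25-34" = 0.12,
            "35-44" = 0.12, "45-54" = 0.13, "55-64" = 0.16, "65-74" = 0.22,
            "75+" = 0.32)
  cells$abstainer_frac <- abst[cells$age_band] +
    ifelse(cells$sex == "female", 0.05, 0)
  cells$n <- n_per_cell
  rownames(cells) <- NULL

  binge <- expand.grid(sex = sexes(), age_band = bands,
                       drinker_level = drinker_levels(),
                       stringsAsFactors = FALSE)
  slope <- c(moderate = 0.30, hazardous = 0.22, harmful = 0.15)
  binge$intercept <- c(moderate = 0.5, hazardous = 1.5,
                       harmful = 3.0)[binge$drinker_level]
  binge$slope <- slope[binge$drinker_level] *
    ifelse(binge$age_band %in% c("18-24", "25-34"), 1.2, 1.0)
  binge$resid_sd <- 1.0
  rownames(binge) <- NULL

  structure(list(cells = cells, binge = binge,
                 preferences = default_beverage_preferences(),
                 share_concentration = 0.5, min_share = 0.02,
                 weight_meanlog = log(100), weight_sdlog = 0.3,
                 seed = seed),
            class = "population_config")
}

# preference weights over 16 categories per sex x age band
default_beverage_preferences <- function() {
  cats <- beverage_categories()
  bands <- age_bands()
  pref <- expand.grid(sex = sexes(), age_band = bands,
                      stringsAsFactors = FALSE)
  base <- c(beer = 0.42, wine = 0.30, spirit = 0.20, rtd = 0.08)
  m <- matrix(0, nrow(pref), length(cats), dimnames = list(NULL, cats))
  young <- pref$age_band %in% c("11-15", "16-17", "18-24")
  for (k in seq_along(cats)) {
    parts <- strsplit(cats[k], "_")[[1]]  # beverage, sector, tier
    w <- base[parts[1]]
    w <- w * ifelse(parts[2] == "on", ifelse(young, 0.65, 0.40),
                    ifelse(young, 0.35, 0.60))
    w <- w * ifelse(parts[3] == "low", ifelse(young, 0.65, 0.45), 0.55)
    if (parts[1] == "rtd") w <- w * ifelse(young, 3.0, 0.6)
    if (parts[1] == "wine") w <- w * ifelse(pref$sex == "female", 1.5, 0.8)
    m[, k] <- w
  }
  pref <- cbind(pref, as.data.frame(m / rowSums(m)))
  rownames(pref) <- NULL
  pref
}

#' Generate a synthetic consumption survey population
#'
#' Draws, per sex x age band cell: abstainer status (Bernoulli), mean weekly
#' units (log-normal), a sparse beverage mix (Dirichlet with small shares
#' zeroed and renormalised) and a peak-day consumption from the linear
#' peak-from-mean model for the individual's drinker level, with a Gaussian
#' residual, floored at the daily share of the mean so the peak is never
#' implausibly below typical daily intake.
#'
#' @param config A [default_population_config()] object.
#' @return Data frame of individuals (one row each) with weight, consumption
#'   and `share_<category>` columns; abstainers have zero consumption and
#'   all-zero shares.
#' @export
generate_population <- function(config = default_population_config()) {
  stopifnot(inherits(config, "population_config"))
  set.seed(config$seed)
  cells <- config$cells
  cats <- beverage_categories()
  out <- vector("list", nrow(cells))
  pid <- 0L
  for (i in seq_len(nrow(cells))) {
    n <- cells$n[i]
    if (n == 0) next
    sex <- cells$sex[i]; band <- cells$age_band[i]
    abst <- stats::runif(n) < cells$abstainer_frac[i]
    mean_units <- ifelse(abst, 0,
                         stats::rlnorm(n, cells$meanlog[i], cells$sdlog[i]))
    lvl <- classify_drinker(sex, mean_units * 8)
    bm <- config$binge
    peak <- numeric(n)
    for (dl in drinker_levels()) {
      sel <- lvl == dl & !abst
      if (!any(sel)) next
      co <- bm[bm$sex == sex & bm$age_band == band & bm$drinker_level == dl, ]
      peak[sel] <- co$intercept + co$slope * mean_units[sel] +
        stats::rnorm(sum(sel), 0, co$resid_sd)
    }
    peak <- pmax(peak, mean_units / 7)
    peak[abst] <- 0
    pr <- config$preferences
    alpha <- as.numeric(pr[pr$sex == sex & pr$age_band == band, cats]) *
      16 * config$share_concentration
    sh <- matrix(stats::rgamma(n * 16, shape = rep(alpha, each = n)), n, 16)
    sh[sh < 0] <- 0
    sh <- sh / pmax(rowSums(sh), 1e-300)
    sh[sh < config$min_share] <- 0
    zero <- rowSums(sh) == 0
    if (any(zero)) sh[zero, which.max(alpha)] <- 1
    sh <- sh / rowSums(sh)
    sh[abst, ] <- 0
    colnames(sh) <- paste0("share_", cats)
    d <- data.frame(person_id = sprintf("p%06d", pid + seq_len(n)),
                    sex = sex, age_band = band,
                    weight = stats::rlnorm(n, config$weight_meanlog,
                                           config$weight_sdlog),
                    mean_weekly_units = mean_units,
                    peak_day_units = peak,
                    stringsAsFactors = FALSE)
    out[[i]] <- cbind(d, as.data.frame(sh))
    pid <- pid + n
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(person_id = character(0), sex = character(0),
                      age_band = character(0), weight = numeric(0),
                      mean_weekly_units = numeric(0),
                      peak_day_units = numeric(0))
    for (cn in paste0("share_", cats)) res[[cn]] <- numeric(0)
  }
  rownames(res) <- NULL
  res
}

#' Default synthetic price configuration
#'
#' Per beverage category: a log-normal distribution of usual prices in pence
#' per unit of ethanol (on-trade dearer than off-trade, the low tier cheaper
#' than the high tier), a discount incidence (share of volume sold below its
#' usual price, concentrated in the off-trade) and a Beta discount-depth
#' distribution.  Also carries ten calibration price points with target
#' cumulative volume shares, emulating the adjustment of diary prices to
#' market-research sales data.
#'
#' @param seed Integer seed used when generating transactions.
#' @return A list of class `price_config`.
#' @export
default_price_config <- function(seed = 99) {
  cats <- beverage_categories()
  parts <- do.call(rbind, strsplit(cats, "_"))
  base <- c(beer = 38, wine = 42, spirit = 36, rtd = 55)  # off-trade low, p/unit
  med <- base[parts[, 1]] *
    ifelse(parts[, 2] == "on", 2.6, 1.0) *
    ifelse(parts[, 3] == "high", 1.7, 1.0)
  prices <- data.frame(category = cats, meanlog = log(med), sdlog = 0.30,
                       discount_incidence = ifelse(parts[, 2] == "off",
                                                   0.30, 0.05),
                       discount_shape1 = 2, discount_shape2 = 6,
                       stringsAsFactors = FALSE)
  rownames(prices) <- NULL
  structure(list(prices = prices,
                 calibration = default_calibration_points(), seed = seed),
            class = "price_config")
}

#' Default price-distribution calibration points
#'
#' Ten price points (pence per unit) with target cumulative volume shares,
#' non-decreasing and ending at 1.
#'
#' @return Data frame with columns `price` and `target_share`.
#' @export
default_calibration_points <- function() {
  data.frame(price = c(20, 30, 40, 50, 65, 80, 100, 150, 250, 600),
             target_share = c(0.02, 0.10, 0.24, 0.40, 0.56, 0.68,
                              0.80, 0.93, 0.99, 1.00))
}

#' Generate synthetic purchasing transactions
#'
#' One transaction per individual x consumed category: ethanol volume equal
#' to the individual's beverage share times mean weekly units (one synthetic
#' week of purchasing), a usual (non-discounted) price drawn per category,
#' and a sold price equal to the usual price reduced by a Beta-distributed
#' discount for the discounted share of volume.  Abstainers generate no
#' transactions.  Ethanol volume is conserved: per drinker, transaction
#' units sum to mean weekly units.
#'
#' @param individuals Data frame from [generate_population()].
#' @param price_config A [default_price_config()] object.
#' @return Data frame of transactions: person_id, category, units,
#'   usual_price, sold_price, weight, drinker_level segment columns are not
#'   attached here (join on person_id as needed).
#' @export
generate_transactions <- function(individuals,
                                  price_config = default_price_config()) {
  stopifnot(inherits(price_config, "price_config"))
  set.seed(price_config$seed)
  cats <- beverage_categories()
  sh <- share_matrix(individuals)
  idx <- which(sh > 0, arr.ind = TRUE)
  if (nrow(idx) == 0)
    return(data.frame(person_id = character(0), category = character(0),
                      units = numeric(0), usual_price = numeric(0),
                      sold_price = numeric(0), weight = numeric(0)))
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  ppar <- price_config$prices
  ci <- idx[, 2]
  usual <- stats::rlnorm(nrow(idx), ppar$meanlog[ci], ppar$sdlog[ci])
  disc <- stats::runif(nrow(idx)) < ppar$discount_incidence[ci]
  depth <- stats::rbeta(nrow(idx), ppar$discount_shape1[ci],
                        ppar$discount_shape2[ci])
  sold <- ifelse(disc, usual * (1 - depth), usual)
  data.frame(person_id = individuals$person_id[idx[, 1]],
             category = cats[ci],
             units = individuals$mean_weekly_units[idx[, 1]] *
               sh[idx],
             usual_price = usual, sold_price = sold,
             weight = individuals$weight[idx[, 1]],
             stringsAsFactors = FALSE)
}

# weighted quantile of x at probabilities p, weights w (volume weights):
# piecewise-linear inverse of the weighted empirical CDF evaluated at the
# midpoint of each atom's weight mass (Harrell-Davis-free, monotone).
weighted_quantile <- function(x, w, p) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  mid <- cw - (w / sum(w)) / 2  # midpoint of each atom's weight mass
  stats::approx(mid, x, xout = p, rule = 2, ties = "ordered")$y
}

# weighted empirical CDF P(x <= q)
weighted_cdf <- function(x, w, q) {
  vapply(q, function(qq) sum(w[x <= qq]) / sum(w), numeric(1))
}

#' Calibrate the sold-price distribution to target cumulative shares
#'
#' Adjusts transaction sold prices by a piecewise-linear monotone map so
#' that the volume-weighted cumulative price distribution matches the target
#' share at each calibration price point, emulating the linear-interpolation
#' adjustment of diary prices to external sales-data price distributions.
#' The map sends the weighted empirical quantile at each target share to the
#' corresponding calibration price and interpolates linearly in between
#' (anchored at zero); volumes, weights and the price ordering are
#' unchanged.  Above the last calibration quantile prices are left
#' unchanged, except that they are clamped up to the last calibration price
#' where needed to keep the map monotone.
#'
#' @param transactions Data frame from [generate_transactions()].
#' @param calibration_points Data frame with strictly increasing `price` and
#'   non-decreasing `target_share` ending at 1 (or below, in which case the
#'   upper tail is untouched).
#' @return `transactions` with adjusted `sold_price` (and `usual_price`
#'   scaled by the same per-transaction factor so sold <= usual still holds).
#' @export
calibrate_price_distribution <- function(transactions, calibration_points) {
  cp <- calibration_points
  if (is.unsorted(cp$price, strictly = TRUE))
    stop("calibration prices must be strictly increasing", call. = FALSE)
  if (is.unsorted(cp$target_share))
    stop("target shares must be non-decreasing", call. = FALSE)
  if (nrow(transactions) == 0) return(transactions)
  w <- transactions$weight * transactions$units
  x <- transactions$sold_price
  q <- weighted_quantile(x, w, cp$target_share)
  # collapse duplicate quantiles (flat CDF regions) keeping monotone knots
  keep <- !duplicated(q)
  qk <- q[keep]; pk <- cp$price[keep]
  ok <- c(TRUE, diff(pk) > 0)
  qk <- qk[ok]; pk <- pk[ok]
  map <- function(v) {
    out <- stats::approx(c(0, qk), c(0, pk), xout = pmin(v, max(qk)),
                         rule = 2, ties = "ordered")$y
    high <- v > max(qk)
    out[high] <- pmax(v[high], max(pk))
    out
  }
  new_sold <- map(x)
  factor <- ifelse(x > 0, new_sold / x, 1)
  transactions$sold_price <- new_sold
  transactions$usual_price <- transactions$usual_price * factor
  transactions
}

#' Default baseline harm configuration
#'
#' A compact synthetic catalogue of alcohol-attributable health conditions
#' covering the four modelled classes (chronic/acute x wholly/partially
#' attributable), with per sex x age band baseline mortality and hospital
#' admission rates (per person-year), attributable fractions for the
#' partially attributable conditions, an annual treatment cost per prevalent
#' case and a utility decrement per prevalent case.  The catalogue is a
#' synthetic desk-scale stand-in for routine burden-of-disease tables; the
#' one value anchored to a published figure is the road-traffic-accident
#' attributable fraction of 0.37 for men aged 25 to 34.
#'
#' @return A list of class `harm_config`: `conditions` (one row per
#'   condition) and `rates` (condition x sex x age band).
#' @export
default_harm_config <- function() {
  conditions <- data.frame(
    condition_id = c("alcoholic_liver_disease", "alcohol_poisoning",
                     "oesophageal_cancer", "hypertensive_disease",
                     "road_traffic_accidents", "falls"),
    timing = c("chronic", "acute", "chronic", "chronic", "acute", "acute"),
    attribution = c("wholly", "wholly", "partially", "partially",
                    "partially", "partially"),
    basis = c("mean_weekly", "peak_day", "mean_weekly", "mean_weekly",
              "peak_day", "peak_day"),
    form = c("two_part_linear", "two_part_linear", "published_curve",
             "published_curve", "two_part_linear", "two_part_linear"),
    stringsAsFactors = FALSE)

  grid <- expand.grid(condition_id = conditions$condition_id,
                      sex = sexes(), age_band = age_bands(),
                      stringsAsFactors = FALSE)
  ai <- match(grid$age_band, age_bands())          # 1..9, rises with age
  base_mort <- c(alcoholic_liver_disease = 8e-5, alcohol_poisoning = 1.5e-5,
                 oesophageal_cancer = 6e-5, hypertensive_disease = 1.2e-4,
                 road_traffic_accidents = 6e-5, falls = 5e-5)
  age_mult <- ifelse(grid$condition_id %in%
                       c("road_traffic_accidents", "alcohol_poisoning"),
                     1 + 0.15 * pmax(4 - ai, 0),   # acute: young-skewed
                     (ai / 4)^2)                    # chronic: old-skewed
  sex_mult <- ifelse(grid$sex == "male", 1.4, 0.8)
  grid$mortality_rate <- base_mort[grid$condition_id] * age_mult * sex_mult
  grid$admission_rate <- grid$mortality_rate * 25
  grid$aaf <- NA_real_
  part <- conditions$condition_id[conditions$attribution == "partially" &
                                    conditions$form == "two_part_linear"]
  sel <- grid$condition_id %in% part
  grid$aaf[sel] <- ifelse(grid$condition_id[sel] == "road_traffic_accidents",
                          0.25, 0.18) *
    ifelse(grid$sex[sel] == "male", 1.2, 0.9)
  grid$aaf[grid$condition_id == "road_traffic_accidents" &
             grid$sex == "male" & grid$age_band == "25-34"] <- 0.37
  grid$aaf <- pmin(grid$aaf, 0.95)
  grid$unit_cost <- c(alcoholic_liver_disease = 4200, alcohol_poisoning = 900,
                      oesophageal_cancer = 9500, hypertensive_disease = 1100,
                      road_traffic_accidents = 2600,
                      falls = 1800)[grid$condition_id]
  grid$utility_decrement <- c(alcoholic_liver_disease = 0.20,
                              alcohol_poisoning = 0.05,
                              oesophageal_cancer = 0.30,
                              hypertensive_disease = 0.08,
                              road_traffic_accidents = 0.12,
                              falls = 0.10)[grid$condition_id]
  rownames(grid) <- NULL

  curves <- list(
    oesophageal_cancer = data.frame(
      units = c(0, 7, 14, 28, 56, 100, 200),
      rr = c(1, 1.15, 1.4, 2.0, 3.2, 5.0, 8.5)),
    hypertensive_disease = data.frame(
      units = c(0, 7, 14, 28, 56, 100, 200),
      rr = c(1, 1.05, 1.2, 1.6, 2.3, 3.1, 4.5)))

  structure(list(conditions = conditions, rates = grid, curves = curves),
            class = "harm_config")
}

#' Build and validate the baseline harm-rate table
#'
#' Checks that the configuration covers every condition x sex x age band
#' cell with rates in [0, 1] and attributable fractions in [0, 1] where the
#' condition is partially attributable, and returns the completed rate
#' table.  Missing cells are reported as a list of gaps.
#'
#' @param harm_config A [default_harm_config()]-shaped list.
#' @return The validated rates data frame.
#' @export
generate_baseline_harms <- function(harm_config = default_harm_config()) {
  rates <- harm_config$rates
  need <- expand.grid(condition_id = harm_config$conditions$condition_id,
                      sex = sexes(), age_band = age_bands(),
                      stringsAsFactors = FALSE)
  key <- function(d) paste(d$condition_id, d$sex, d$age_band, sep = "|")
  gaps <- setdiff(key(need), key(rates))
  if (length(gaps))
    stop("harm config missing cells: ", paste(gaps, collapse = "; "),
         call. = FALSE)
  if (any(rates$mortality_rate < 0 | rates$mortality_rate > 1) ||
      any(rates$admission_rate < 0 | rates$admission_rate > 1))
    stop("rates must lie in [0, 1] per person-year", call. = FALSE)
  aaf <- rates$aaf[!is.na(rates$aaf)]
  if (any(aaf < 0 | aaf > 1))
    stop("AAF values must lie in [0, 1]", call. = FALSE)
  rates
}
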