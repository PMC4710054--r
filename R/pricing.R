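# Pricing policies on the transaction price distribution ---------------------

#' Declare a policy
#'
#' A declarative description of one intervention on the price distribution
#' or, for availability/advertising what-ifs, directly on consumption.
#'
#' @param kind One of `minimum_unit_price`, `general_price_change`,
#'   `low_priced_change`, `discount_restriction`,
#'   `relative_consumption_change`.
#' @param name Display label.
#' @param floor Price floor, pence per unit (minimum unit price).
#' @param percent Percent price change (`general_price_change`,
#'   `low_priced_change`) or percent consumption change
#'   (`relative_consumption_change`).
#' @param cutoff Low-price cut-off in pence/unit (`low_priced_change`), or a
#'   usual-price cut-off restricting a discount ban to cheap products.
#' @param max_discount Maximum permitted discount fraction in [0, 1]
#'   (`discount_restriction`); 0 is a total ban.
#' @param scope `"on_trade"`, `"off_trade"` or `"both"`.
#' @param beverages Optional beverage restriction: any of `"beer"`,
#'   `"wine"`, `"spirit"`, `"rtd"`; NULL means all.
#' @return An object of class `policy`.
#' @export
policy <- function(kind, name = kind, floor = NULL, percent = NULL,
                   cutoff = NULL, max_discount = NULL, scope = "both",
                   beverages = NULL) {
  kinds <- c("minimum_unit_price", "general_price_change",
             "low_priced_change", "discount_restriction",
             "relative_consumption_change")
  if (!kind %in% kinds)
    stop("unknown policy kind: ", kind, call. = FALSE)
  if (!scope %in% c("on_trade", "off_trade", "both"))
    stop("invalid scope", call. = FALSE)
  if (kind == "minimum_unit_price" && (is.null(floor) || floor <= 0))
    stop("minimum_unit_price requires floor > 0", call. = FALSE)
  if (kind %in% c("general_price_change", "low_priced_change",
                  "relative_consumption_change")) {
    if (is.null(percent) || percent <= -100)
      stop(kind, " requires percent > -100", call. = FALSE)
  }
  if (kind == "low_priced_change" && is.null(cutoff))
    stop("low_priced_change requires a cutoff", call. = FALSE)
  if (kind == "discount_restriction") {
    if (is.null(max_discount) || max_discount < 0 || max_discount > 1)
      stop("discount_restriction requires max_discount in [0, 1]",
           call. = FALSE)
  }
  structure(list(kind = kind, name = name, floor = floor, percent = percent,
                 cutoff = cutoff, max_discount = max_discount, scope = scope,
                 beverages = beverages),
            class = "policy")
}

#' @export
print.policy <- function(x, ...) {
  det <- switch(x$kind,
    minimum_unit_price = sprintf("floor %gp/unit", x$floor),
    general_price_change = sprintf("%+g%% prices", x$percent),
    low_priced_change = sprintf("%+g%% prices below %gp/unit",
                                x$percent, x$cutoff),
    discount_restriction = if (x$max_discount == 0) "total discount ban"
      else sprintf("discounts capped at %g%%", 100 * x$max_discount),
    relative_consumption_change = sprintf("%+g%% consumption", x$percent))
  cat(sprintf("<policy> %s: %s [%s]\n", x$name, det, x$scope))
  invisible(x)
}

# logical: which transactions are in scope for this policy
in_scope <- function(transactions, pol) {
  sector <- ifelse(grepl("_on_", transactions$category), "on_trade",
                   "off_trade")
  ok <- pol$scope == "both" | sector == pol$scope
  if (!is.null(pol$beverages)) {
    bev <- sub("_.*", "", transactions$category)
    ok <- ok & bev %in% pol$beverages
  }
  ok
}

#' Apply a minimum unit price
#'
#' Every in-scope sold price below the floor rises to exactly the floor;
#' prices at or above it, and all volumes and weights, are unchanged.  The
#' transformation is monotone and idempotent.
#'
#' @param transactions Transaction table.
#' @param floor Price floor, pence per unit (> 0).
#' @param scope Sector scope; see [policy()].
#' @param beverages Optional beverage restriction.
#' @return Adjusted transaction table.
#' @export
apply_minimum_unit_price <- function(transactions, floor, scope = "both",
                                     beverages = NULL) {
  stopifnot(floor > 0)
  pol <- policy("minimum_unit_price", floor = floor, scope = scope,
                beverages = beverages)
  sel <- in_scope(transactions, pol)
  transactions$sold_price[sel] <- pmax(transactions$sold_price[sel], floor)
  transactions$usual_price[sel] <- pmax(transactions$usual_price[sel], floor)
  transactions
}

#' Apply a general or low-price-targeted percent price change
#'
#' Multiplies in-scope sold and usual prices by (1 + percent/100); when
#' `cutoff` is given only transactions with sold price below the cutoff are
#' affected (targeted low-price rise).
#'
#' @inheritParams apply_minimum_unit_price
#' @param percent Percent change, > -100.
#' @param cutoff Optional pence/unit cut-off restricting the change to
#'   low-priced products.
#' @return Adjusted transaction table.
#' @export
apply_general_price_change <- function(transactions, percent, scope = "both",
                                       cutoff = NULL, beverages = NULL) {
  if (percent <= -100)
    stop("percent must be > -100", call. = FALSE)
  pol <- policy("general_price_change", percent = percent, scope = scope,
                beverages = beverages)
  sel <- in_scope(transactions, pol)
  if (!is.null(cutoff)) sel <- sel & transactions$sold_price < cutoff
  f <- 1 + percent / 100
  transactions$sold_price[sel] <- transactions$sold_price[sel] * f
  transactions$usual_price[sel] <- transactions$usual_price[sel] * f
  transactions
}

#' Apply a discount restriction
#'
#' Raises each in-scope sold price to at least
#' `usual_price * (1 - max_discount)`.  A total ban (`max_discount = 0`)
#' makes every sold price equal its usual price.  With `usual_cutoff` the
#' restriction applies only to products whose usual price is below the
#' cutoff (e.g. banning discounts on cheap products only).
#'
#' @inheritParams apply_minimum_unit_price
#' @param max_discount Maximum permitted discount fraction in [0, 1].
#' @param usual_cutoff Optional usual-price cutoff (pence/unit).
#' @return Adjusted transaction table.
#' @export
apply_discount_restriction <- function(transactions, max_discount,
                                       scope = "both", usual_cutoff = NULL,
                                       beverages = NULL) {
  stopifnot(max_discount >= 0, max_discount <= 1)
  pol <- policy("discount_restriction", max_discount = max_discount,
                scope = scope, beverages = beverages)
  sel <- in_scope(transactions, pol)
  if (!is.null(usual_cutoff))
    sel <- sel & transactions$usual_price < usual_cutoff
  permitted_floor <- transactions$usual_price[sel] * (1 - max_discount)
  transactions$sold_price[sel] <- pmax(transactions$sold_price[sel],
                                       permitted_floor)
  transactions
}

#' Apply one price policy to a transaction table
#'
#' Dispatch on policy kind.  `relative_consumption_change` policies do not
#' touch prices and return the table unchanged (their effect is applied to
#' consumption directly; see [apply_relative_change()]).
#'
#' @param transactions Transaction table.
#' @param pol A [policy()] object, or a list of them applied sequentially in
#'   the order given (order matters: a price floor and a percent rise do not
#'   commute).
#' @return Adjusted transaction table.
#' @export
apply_policy <- function(transactions, pol) {
  if (!inherits(pol, "policy") && is.list(pol)) {
    for (p in pol) transactions <- apply_policy(transactions, p)
    return(transactions)
  }
  switch(pol$kind,
    minimum_unit_price = apply_minimum_unit_price(
      transactions, pol$floor, pol$scope, pol$beverages),
    general_price_change = apply_general_price_change(
      transactions, pol$percent, pol$scope, beverages = pol$beverages),
    low_priced_change = apply_general_price_change(
      transactions, pol$percent, pol$scope, cutoff = pol$cutoff,
      beverages = pol$beverages),
    discount_restriction = apply_discount_restriction(
      transactions, pol$max_discount, pol$scope,
      usual_cutoff = pol$cutoff, beverages = pol$beverages),
    relative_consumption_change = transactions)
}

#' Mean percent price change per beverage category and demand segment
#'
#' Compares aligned before/after transaction tables and reports, per demand
#' segment (moderate vs hazardous+harmful) and per category, the percent
#' change of the volume-weighted mean sold price, weighting each transaction
#' by `weight * units` (ethanol-volume weighting, the model's per-unit
#' currency).  Categories with no volume in a segment report 0.
#'
#' @param before,after Transaction tables, row-aligned (same transactions,
#'   different prices).
#' @param segment_of Named character vector mapping person_id to
#'   `"moderate"` or `"hazardous_harmful"`.
#' @return A list with one numeric length-16 vector per segment, named by
#'   [beverage_categories()].
#' @export
mean_price_change_vector <- function(before, after, segment_of) {
  if (nrow(before) != nrow(after) ||
      !identical(before$person_id, after$person_id) ||
      !identical(before$category, after$category))
    stop("before/after transaction tables are not aligned", call. = FALSE)
  cats <- beverage_categories()
  seg <- unname(segment_of[before$person_id])
  if (any(is.na(seg)))
    stop("segment_of does not cover every person", call. = FALSE)
  w <- before$weight * before$units
  out <- list()
  for (s in c("moderate", "hazardous_harmful")) {
    sel <- seg == s
    res <- numeric(length(cats)); names(res) <- cats
    if (any(sel)) {
      wb <- tapply(w[sel] * before$sold_price[sel], factor(before$category[sel],
                   levels = cats), sum, default = 0)
      wa <- tapply(w[sel] * after$sold_price[sel], factor(after$category[sel],
                   levels = cats), sum, default = 0)
      ww <- tapply(w[sel], factor(before$category[sel], levels = cats),
                   sum, default = 0)
      pos <- !is.na(ww) & ww > 0
      res[pos] <- 100 * (wa[pos] / ww[pos] - wb[pos] / ww[pos]) /
        (wb[pos] / ww[pos])
    }
    out[[s]] <- res
  }
  out
}

#' Demand segment of each individual
#'
#' Elasticities are estimated for two broad segments: moderate drinkers and
#' hazardous+harmful drinkers combined.  Segment membership is fixed at the
#' baseline drinker level throughout a simulation.
#'
#' @param individuals Output of [assign_subgroups()].
#' @return Named character vector (by person_id).
#' @export
demand_segments <- function(individuals) {
  seg <- ifelse(individuals$drinker_level == "moderate",
                "moderate", "hazardous_harmful")
  names(seg) <- individuals$person_id
  seg
}

#' The fixture library of appraised policies
#'
#' Eighteen policy scenarios spanning general price rises, low-price
#' targeted rises, minimum unit prices, discount restrictions and
#' availability/advertising what-ifs (the latter expressed as relative
#' consumption changes, with the what-if percentages shipped as inputs).
#'
#' @return Named list of [policy()] objects (or lists of policies applied
#'   sequentially).
#' @export
policy_library <- function() {
  list(
    "General price +10%" =
      policy("general_price_change", "General price +10%", percent = 10),
    "General price +25%" =
      policy("general_price_change", "General price +25%", percent = 25),
    "Low priced off trade products +25%" =
      policy("low_priced_change", "Low priced off trade products +25%",
             percent = 25, cutoff = 40, scope = "off_trade"),
    "Low priced on trade products +25%" =
      policy("low_priced_change", "Low priced on trade products +25%",
             percent = 25, cutoff = 100, scope = "on_trade"),
    "All low priced products +10%" = list(
      policy("low_priced_change", "All low priced off +10%",
             percent = 10, cutoff = 40, scope = "off_trade"),
      policy("low_priced_change", "All low priced on +10%",
             percent = 10, cutoff = 100, scope = "on_trade")),
    "Minimum price 15p" =
      policy("minimum_unit_price", "Minimum price 15p", floor = 15),
    "Minimum price 25p" =
      policy("minimum_unit_price", "Minimum price 25p", floor = 25),
    "Minimum price 50p" =
      policy("minimum_unit_price", "Minimum price 50p", floor = 50),
    "Minimum price 70p" =
      policy("minimum_unit_price", "Minimum price 70p", floor = 70),
    "Minimum price 40p off / 100p on" = list(
      policy("minimum_unit_price", "40p off-trade floor", floor = 40,
             scope = "off_trade"),
      policy("minimum_unit_price", "100p on-trade floor", floor = 100,
             scope = "on_trade")),
    "30p minimum price beers only" =
      policy("minimum_unit_price", "30p minimum price beers only",
             floor = 30, beverages = "beer"),
    "Ban off trade discounting >50%" =
      policy("discount_restriction", "Ban off trade discounting >50%",
             max_discount = 0.5, scope = "off_trade"),
    "Ban off trade discounting >20%" =
      policy("discount_restriction", "Ban off trade discounting >20%",
             max_discount = 0.2, scope = "off_trade"),
    "Total ban off trade discounting" =
      policy("discount_restriction", "Total ban off trade discounting",
             max_discount = 0, scope = "off_trade"),
    "Ban off trade discount if usual <30p" =
      policy("discount_restriction", "Ban off trade discount if usual <30p",
             max_discount = 0, cutoff = 30, scope = "off_trade"),
    "Total advertising ban" =
      policy("relative_consumption_change", "Total advertising ban",
             percent = -26.9),
    "10% reduction in outlet density" =
      policy("relative_consumption_change",
             "10% reduction in outlet density", percent = 13.2),
    "10% reduction in licensing hours" =
      policy("relative_consumption_change",
             "10% reduction in licensing hours", percent = -1.2)
  )
}

#' Read a policy file
#'
#' Policies are declared in a structured YAML file, one entry per policy
#' with `kind` and parameters (see the shipped fixture at
#' `system.file("extdata", "policy_library.yaml", package = "alcpolicy")`).
#' An entry with a `steps` list becomes a sequence of policies applied in
#' the order given; order matters and is preserved.
#'
#' @param path YAML file path.
#' @return Named list of [policy()] objects (or lists of them).
#' @export
read_policy_file <- function(path) {
  spec <- yaml::read_yaml(path)$policies
  build <- function(e, name) {
    policy(e$kind, name = name, floor = e$floor, percent = e$percent,
           cutoff = e$cutoff, max_discount = e$max_discount,
           scope = if (is.null(e$scope)) "both" else e$scope,
           beverages = unlist(e$beverages))
  }
  out <- lapply(spec, function(e) {
    if (!is.null(e$steps)) lapply(e$steps, build, name = e$name)
    else build(e, e$name)
  })
  names(out) <- vapply(spec, `[[`, character(1), "name")
  out
}

#' Expand a usual-by-sold price band matrix into synthetic transactions
#'
#' Discount patterns can be supplied as a 10 x 10 matrix of volume shares
#' (rows: usual-price band, columns: sold-price band).  Each non-zero cell
#' becomes one synthetic transaction at the band midpoints, carrying the
#' cell's volume share as units.
#'
#' @param band_matrix Numeric matrix, rows/cols named by band lower bounds
#'   in pence/unit.
#' @param band_width Band width in pence/unit.
#' @param category Beverage category for the generated transactions.
#' @param total_units Total ethanol volume represented by the matrix.
#' @return Transaction table.
#' @export
expand_discount_bands <- function(band_matrix, band_width = 5,
                                  category = "beer_off_low",
                                  total_units = 1) {
  ub <- as.numeric(rownames(band_matrix)) + band_width / 2
  sb <- as.numeric(colnames(band_matrix)) + band_width / 2
  idx <- which(band_matrix > 0, arr.ind = TRUE)
  data.frame(person_id = sprintf("band%03d", seq_len(nrow(idx))),
             category = category,
             units = band_matrix[idx] / sum(band_matrix) * total_units,
             usual_price = ub[idx[, 1]],
             sold_price = pmin(sb[idx[, 2]], ub[idx[, 1]]),
             weight = 1, stringsAsFactors = FALSE)
}
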