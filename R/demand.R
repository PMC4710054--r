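# Demand response: elasticities, consumption and peak updates ----------------

#' Construct an elasticity matrix
#'
#' Entry (i, j) is the percent change in consumption of category i per 1 %
#' change in the price of category j; diagonal entries are own-price
#' elasticities (typically negative), off-diagonal entries cross-price
#' elasticities.  A positive diagonal entry triggers a warning but is not
#' rejected.
#'
#' @param m 16 x 16 numeric matrix (rows/cols in [beverage_categories()]
#'   order).
#' @param segment `"moderate"` or `"hazardous_harmful"`.
#' @return Object of class `elasticity_matrix`.
#' @export
elasticity_matrix <- function(m, segment = "moderate") {
  cats <- beverage_categories()
  m <- as.matrix(m)
  if (!all(dim(m) == c(16, 16)))
    stop("elasticity matrix must be 16 x 16", call. = FALSE)
  if (any(!is.finite(m)))
    stop("elasticity entries must be finite", call. = FALSE)
  if (any(diag(m) > 0))
    warning("positive own-price elasticity on the diagonal")
  dimnames(m) <- list(cats, cats)
  structure(m, class = c("elasticity_matrix", "matrix"),
            segment = segment)
}

#' Default synthetic elasticity matrices
#'
#' Deterministic synthetic 16 x 16 own-/cross-price elasticity matrices for
#' the two demand segments, standing in for econometric estimates (which are
#' inputs to this model, not outputs).  Own-price elasticities lie around
#' -0.4 to -1.0 (heavier for the on-trade and the RTD categories); small
#' positive cross-price terms link the low and high tiers of the same
#' beverage and sector (substitution), with the hazardous+harmful segment
#' slightly more price-responsive than the moderate segment, so that the
#' population-average own-price response is of the order published
#' meta-analyses report (around -0.5).
#'
#' @return Named list with `moderate` and `hazardous_harmful`
#'   [elasticity_matrix()] objects.
#' @export
default_elasticities <- function() {
  cats <- beverage_categories()
  parts <- do.call(rbind, strsplit(cats, "_"))
  own <- -(0.45 + 0.10 * (parts[, 2] == "on") + 0.25 * (parts[, 1] == "rtd") +
             0.08 * (parts[, 3] == "high"))
  build <- function(scale) {
    m <- matrix(0, 16, 16, dimnames = list(cats, cats))
    diag(m) <- own * scale
    for (i in 1:16) for (j in 1:16) {
      if (i == j) next
      same_bev <- parts[i, 1] == parts[j, 1]
      same_sec <- parts[i, 2] == parts[j, 2]
      if (same_bev && same_sec) m[i, j] <- 0.12 * scale   # tier substitution
      else if (same_bev)        m[i, j] <- 0.04 * scale   # cross-sector
      else if (same_sec && parts[i, 3] == parts[j, 3])
        m[i, j] <- 0.015 * scale                           # mild substitution
    }
    m
  }
  list(moderate = elasticity_matrix(build(0.92), "moderate"),
       hazardous_harmful = elasticity_matrix(build(1.08),
                                             "hazardous_harmful"))
}

#' Consumption change from price changes
#'
#' First-order elasticity application in the percent domain:
#' `delta_c = E %*% delta_p`, where E is the 16 x 16 elasticity matrix and
#' delta_p the vector of mean percent price changes.  Additive in price
#' changes by construction.
#'
#' @param price_changes Numeric length-16 vector of percent price changes.
#' @param elasticity An [elasticity_matrix()].
#' @param multiplicative If TRUE use the multiplicative variant
#'   `100 * (prod_j (1 + dp_j/100)^E_ij - 1)` instead (sensitivity option;
#'   agrees with the first-order form for small changes).
#' @return Numeric length-16 vector of percent consumption changes.
#' @export
consumption_change_vector <- function(price_changes, elasticity,
                                      multiplicative = FALSE) {
  if (length(price_changes) != 16)
    stop("price_changes must have length 16", call. = FALSE)
  if (multiplicative) {
    lg <- log1p(price_changes / 100)
    return(100 * expm1(as.vector(unclass(elasticity) %*% lg)))
  }
  out <- as.vector(unclass(elasticity) %*% price_changes)
  names(out) <- beverage_categories()
  out
}

#' Apply category consumption changes to individuals
#'
#' Each drinker's consumption by category (share x mean weekly units) is
#' scaled by (1 + delta_c/100) for that category, floored at zero; the new
#' mean is the sum over categories and the shares are re-normalised over the
#' new mix.  Abstainers are unchanged.  Changes may be supplied per segment
#' (a list keyed by `moderate`/`hazardous_harmful`, applied by each
#' individual's baseline segment) or as a single vector for all.
#'
#' @param individuals Output of [assign_subgroups()].
#' @param category_changes Length-16 percent vector, or a list of two such
#'   vectors keyed by segment.
#' @param coverage Fraction of each segment affected (1 = whole segment;
#'   intervention-style partial uptake scales the percent change).
#' @return Updated individuals (mean_weekly_units and shares revised).
#' @export
apply_consumption_change <- function(individuals, category_changes,
                                     coverage = 1) {
  if (nrow(individuals) == 0) return(individuals)
  sh <- share_matrix(individuals)
  if (is.list(category_changes)) {
    seg <- demand_segments(individuals)
    dc <- t(vapply(unname(seg), function(s) category_changes[[s]],
                   numeric(16)))
  } else {
    dc <- matrix(category_changes, nrow(individuals), 16, byrow = TRUE)
  }
  fac <- pmax(1 + coverage * dc / 100, 0)
  units <- sh * individuals$mean_weekly_units
  new_units <- units * fac
  new_mean <- rowSums(new_units)
  drinker <- individuals$mean_weekly_units > 0
  new_sh <- sh
  pos <- drinker & new_mean > 0
  new_sh[pos, ] <- new_units[pos, , drop = FALSE] / new_mean[pos]
  individuals$mean_weekly_units[drinker] <- new_mean[drinker]
  individuals[, paste0("share_", beverage_categories())] <- new_sh
  individuals
}

#' Update peak-day consumption after a mean change
#'
#' Linear peak-from-mean model: `peak' = max(0, peak + slope * (new - old))`
#' with the slope from the individual's sex x age band x drinker-level cell.
#' Shifting by the slope times the mean change preserves each individual's
#' residual around the linear fit.
#'
#' @param individuals Output of [assign_subgroups()] (drinker_level present,
#'   at baseline).
#' @param old_mean,new_mean Numeric vectors of mean weekly units before and
#'   after the change.
#' @param binge_model Data frame with sex, age_band, drinker_level, slope
#'   (e.g. `default_population_config()$binge`).
#' @return Updated individuals with revised `peak_day_units`.
#' @export
update_peak <- function(individuals, old_mean, new_mean, binge_model) {
  if (nrow(individuals) == 0) return(individuals)
  key <- paste(individuals$sex, individuals$age_band,
               individuals$drinker_level, sep = "|")
  mkey <- paste(binge_model$sex, binge_model$age_band,
                binge_model$drinker_level, sep = "|")
  idx <- match(key, mkey)
  if (any(is.na(idx)))
    stop("binge model missing coefficients for: ",
         paste(unique(key[is.na(idx)]), collapse = ", "), call. = FALSE)
  slope <- binge_model$slope[idx]
  individuals$peak_day_units <-
    pmax(0, individuals$peak_day_units + slope * (new_mean - old_mean))
  individuals
}

#' Apply a relative consumption change (availability/advertising what-if)
#'
#' Scales every drinker's mean weekly units by (1 + percent/100) and updates
#' peak-day consumption through the linear peak-from-mean model.  Abstainers
#' are unchanged.
#'
#' @param individuals Output of [assign_subgroups()].
#' @param percent Percent change, > -100.
#' @param binge_model See [update_peak()].
#' @return Updated individuals.
#' @export
apply_relative_change <- function(individuals, percent, binge_model) {
  if (percent <= -100) stop("percent must be > -100", call. = FALSE)
  old <- individuals$mean_weekly_units
  new <- old * (1 + percent / 100)
  individuals$mean_weekly_units <- new
  update_peak(individuals, old, new, binge_model)
}

# lower-triangular PSD factor: cholesky when positive definite, eigen-based
# square root otherwise (covers the degenerate zero-covariance case)
psd_factor <- function(cov, tol = 1e-10) {
  cov <- (cov + t(cov)) / 2
  ev <- eigen(cov, symmetric = TRUE)
  if (min(ev$values) < -tol * max(abs(ev$values), 1))
    stop("covariance matrix is not positive semi-definite", call. = FALSE)
  pd <- tryCatch(t(chol(cov)), error = function(e) NULL)
  if (!is.null(pd)) return(pd)
  ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), nrow(cov))
}

#' Sample elasticity matrices from coefficient uncertainty
#'
#' Multivariate-normal draws of the (vectorised) elasticity coefficients
#' from a mean vector and covariance matrix via a triangular/PSD factor of
#' the covariance, for probabilistic sensitivity analysis.  Reproducible
#' given the seed.
#'
#' @param mean Numeric vector of mean coefficients (length 256 for a full
#'   16 x 16 matrix, but any length is accepted).
#' @param cov Covariance matrix (symmetric PSD) of the coefficients.
#' @param n_draws Number of draws (>= 1).
#' @param seed Integer seed.
#' @param segment Segment label attached to the returned matrices when
#'   `length(mean) == 256`.
#' @return If `length(mean) == 256`, a list of [elasticity_matrix()]
#'   objects; otherwise a matrix with one draw per row.
#' @export
sample_elasticity_matrices <- function(mean, cov, n_draws, seed = 1,
                                       segment = "moderate") {
  stopifnot(n_draws >= 1, length(mean) == nrow(cov), nrow(cov) == ncol(cov))
  L <- psd_factor(cov)
  set.seed(seed)
  z <- matrix(stats::rnorm(n_draws * length(mean)), length(mean), n_draws)
  draws <- t(mean + L %*% z)
  if (length(mean) == 256) {
    lapply(seq_len(n_draws), function(i) {
      suppressWarnings(
        elasticity_matrix(matrix(draws[i, ], 16, 16), segment))
    })
  } else draws
}

#' Read / write an elasticity matrix as labelled CSV
#'
#' 16 rows x 16 columns with category labels in the first column/header.
#'
#' @param path File path.
#' @param segment Segment label for the constructed object.
#' @return For `read_elasticity_csv`, an [elasticity_matrix()].
#' @export
read_elasticity_csv <- function(path, segment = "moderate") {
  x <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  elasticity_matrix(as.matrix(x[beverage_categories(),
                                beverage_categories()]), segment)
}

#' @rdname read_elasticity_csv
#' @param e An [elasticity_matrix()].
#' @export
write_elasticity_csv <- function(e, path) {
  utils::write.csv(as.data.frame(unclass(e)), path)
  invisible(path)
}
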