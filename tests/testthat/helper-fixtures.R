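# Small in-code fixtures shared across test files.

# a hand-built microdata table with known classifications
tiny_population <- function() {
  cats <- beverage_categories()
  sh <- matrix(0, 4, 16, dimnames = list(NULL, paste0("share_", cats)))
  sh[1, c(1, 2)] <- c(0.5, 0.5)   # two-category drinker
  sh[2, 3] <- 1                   # single-category drinker
  sh[3, 5] <- 1
  d <- data.frame(person_id = c("a", "b", "c", "d"),
                  sex = c("male", "male", "female", "female"),
                  age_band = c("18-24", "25-34", "25-34", "35-44"),
                  weight = c(10, 20, 30, 40),
                  mean_weekly_units = c(10, 60, 40, 0),  # mod/harm/harm/abst
                  peak_day_units = c(4, 15, 9, 0),
                  stringsAsFactors = FALSE)
  cbind(d, as.data.frame(sh))
}

# a hand-built transaction table
tiny_transactions <- function() {
  data.frame(person_id = c("a", "a", "b", "c"),
             category = c("beer_off_low", "wine_on_high",
                          "spirit_off_low", "beer_on_low"),
             units = c(5, 5, 60, 40),
             usual_price = c(40, 150, 35, 90),
             sold_price = c(30, 150, 28, 90),
             weight = c(10, 10, 20, 30),
             stringsAsFactors = FALSE)
}

# seeded synthetic population of moderate size for statistical tests
synth_population <- function(n_per_cell = 60, seed = 11) {
  cfg <- default_population_config(n_per_cell = n_per_cell, seed = seed)
  assign_subgroups(generate_population(cfg))
}

# random consumption state + weights for property tests
random_state <- function(n, seed) {
  set.seed(seed)
  list(consumption = rlnorm(n, log(8), 1),
       weights = runif(n, 0.5, 2))
}

# brute-force grid search for the two-part slope that best matches a target
# AAF (independent oracle for the closed-form calibration)
grid_search_slope <- function(consumption, weights, threshold, target_aaf,
                              s_max, n_grid = 10000) {
  grid <- seq(0, s_max, length.out = n_grid)
  aafs <- vapply(grid, function(s) {
    rr <- 1 + s * pmax(consumption - threshold, 0)
    sum(weights * (rr - 1)) / sum(weights * rr)
  }, numeric(1))
  grid[which.min(abs(aafs - target_aaf))]
}

# two-stage grid search: a coarse 10,000-point bracket over [0, s_max]
# refined by a second 10,000-point grid inside the bracketing step, giving a
# resolution of s_max / 10^7 (well below 1e-6 for unit-scale slopes) while
# using only oracle AAF evaluations
refined_grid_slope <- function(consumption, weights, threshold, target_aaf,
                               s_max = 10) {
  s1 <- grid_search_slope(consumption, weights, threshold, target_aaf,
                          s_max)
  step <- s_max / 9999
  lo <- max(0, s1 - step)
  grid <- seq(lo, s1 + step, length.out = 10000)
  aafs <- vapply(grid, function(s) {
    rr <- 1 + s * pmax(consumption - threshold, 0)
    sum(weights * (rr - 1)) / sum(weights * rr)
  }, numeric(1))
  grid[which.min(abs(aafs - target_aaf))]
}
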