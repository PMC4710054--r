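test_that("minimum unit price floors sub-floor prices exactly and is idempotent", {
  tx <- tiny_transactions()  # sold prices 30, 150, 28, 90
  out <- apply_minimum_unit_price(tx, 50)
  expect_equal(out$sold_price, c(50, 150, 50, 90))
  expect_equal(out$units, tx$units)
  expect_equal(out$weight, tx$weight)
  expect_equal(min(out$sold_price), 50)
  # idempotence
  expect_equal(apply_minimum_unit_price(out, 50), out)
  # a floor below the observed minimum is the identity
  expect_equal(apply_minimum_unit_price(tx, min(tx$sold_price) - 0.01), tx)
  # scope: off-trade floor leaves on-trade untouched
  off <- apply_minimum_unit_price(tx, 100, scope = "off_trade")
  expect_equal(off$sold_price, c(100, 150, 100, 90))
  expect_error(apply_minimum_unit_price(tx, 0))
})

test_that("general and low-price changes multiply the right prices", {
  tx <- tiny_transactions()
  up <- apply_general_price_change(tx, 10)
  expect_equal(up$sold_price, tx$sold_price * 1.1)
  expect_equal(apply_general_price_change(tx, 0), tx)
  # +25% only below a 30p cutoff
  low <- apply_general_price_change(tx, 25, cutoff = 30)
  expect_equal(low$sold_price, c(30, 150, 35, 90))
  expect_error(apply_general_price_change(tx, -100), "-100")
})

test_that("discount restrictions raise sold prices to the permitted floor", {
  tx <- data.frame(person_id = "x", category = "beer_off_low", units = 1,
                   usual_price = 100, sold_price = 40, weight = 1,
                   stringsAsFactors = FALSE)
  expect_equal(apply_discount_restriction(tx, 0.5)$sold_price, 50)
  # total ban: sold = usual for all
  tx2 <- tiny_transactions()
  ban <- apply_discount_restriction(tx2, 0)
  expect_equal(ban$sold_price, ban$usual_price)
  # sold already above the permitted floor stays put
  expect_equal(apply_discount_restriction(tx, 0.7)$sold_price, 40)
})

test_that("price transformations preserve price ordering", {
  pop <- synth_population(n_per_cell = 20, seed = 31)
  tx <- generate_transactions(pop, default_price_config(seed = 2))
  for (f in list(function(t) apply_minimum_unit_price(t, 45),
                 function(t) apply_general_price_change(t, 15))) {
    out <- f(tx)
    o <- order(tx$sold_price)
    expect_true(all(diff(out$sold_price[o]) > -1e-9))
    expect_equal(out$units, tx$units)
  }
  # a discount restriction depends on the usual/sold pair, so ordering of
  # sold prices alone can change; it never lowers a price and never pushes
  # sold above usual
  dr <- apply_discount_restriction(tx, 0.1)
  expect_true(all(dr$sold_price >= tx$sold_price - 1e-12))
  expect_true(all(dr$sold_price <= dr$usual_price + 1e-9))
  expect_equal(dr$units, tx$units)
})

test_that("mean price change vector matches a brute-force weighted-mean oracle", {
  pop <- synth_population(n_per_cell = 20, seed = 33)
  tx <- generate_transactions(pop, default_price_config(seed = 4))
  seg <- demand_segments(pop)
  after <- apply_minimum_unit_price(tx, 50)
  v <- mean_price_change_vector(tx, after, seg)

  # identical tables give all zeros
  z <- mean_price_change_vector(tx, tx, seg)
  expect_true(all(unlist(z) == 0))

  # oracle: explicit weighted sums per segment x category
  for (s in c("moderate", "hazardous_harmful")) {
    sel <- unname(seg[tx$person_id]) == s
    for (cat in beverage_categories()) {
      rows <- sel & tx$category == cat
      expected <- if (!any(rows)) 0 else {
        w <- tx$weight[rows] * tx$units[rows]
        pb <- sum(w * tx$sold_price[rows]) / sum(w)
        pa <- sum(w * after$sold_price[rows]) / sum(w)
        100 * (pa - pb) / pb
      }
      expect_equal(unname(v[[s]][cat]), expected, tolerance = 1e-10)
    }
  }

  # a floor at/below the observed minimum yields a zero vector
  low <- apply_minimum_unit_price(tx, min(tx$sold_price))
  expect_true(all(abs(unlist(mean_price_change_vector(tx, low, seg)))
                  < 1e-12))

  # single transaction 40 -> 44 is +10% in its category
  one <- tiny_transactions()[1, ]
  one$sold_price <- 40
  one_after <- one
  one_after$sold_price <- 44
  seg1 <- c(a = "moderate")
  v1 <- mean_price_change_vector(one, one_after, seg1)
  expect_equal(unname(v1$moderate["beer_off_low"]), 10)

  # misaligned tables are rejected
  expect_error(mean_price_change_vector(tx[-1, ], after, seg), "aligned")
})

test_that("the fixture policy library holds the 18 appraised scenarios", {
  lib <- policy_library()
  expect_length(lib, 18)
  kinds <- vapply(lib, function(p)
    if (inherits(p, "policy")) p$kind else "composite", character(1))
  expect_equal(sum(kinds == "minimum_unit_price"), 5)  # 15/25/50/70/30p-beer
  expect_equal(sum(kinds == "relative_consumption_change"), 3)
  # sequential composition is order-dependent and supported
  tx <- tiny_transactions()
  seqd <- apply_policy(tx, lib[["Minimum price 40p off / 100p on"]])
  expect_true(all(seqd$sold_price[grepl("_off_", seqd$category)] >= 40))
  expect_true(all(seqd$sold_price[grepl("_on_", seqd$category)] >= 100))
})

test_that("the shipped policy file reproduces the in-code library", {
  f <- system.file("extdata", "policy_library.yaml", package = "alcpolicy")
  from_file <- read_policy_file(f)
  lib <- policy_library()
  expect_identical(names(from_file), names(lib))
  # applying either declaration to the same transactions agrees
  tx <- tiny_transactions()
  for (nm in names(lib))
    expect_equal(apply_policy(tx, from_file[[nm]]),
                 apply_policy(tx, lib[[nm]]))
})

test_that("discount band matrices expand to volume-conserving transactions", {
  m <- matrix(0, 3, 3, dimnames = list(c(30, 35, 40), c(30, 35, 40)))
  m[2, 1] <- 0.3; m[3, 2] <- 0.2; m[3, 3] <- 0.5
  tx <- expand_discount_bands(m, band_width = 5, total_units = 100)
  expect_equal(sum(tx$units), 100)
  expect_true(all(tx$sold_price <= tx$usual_price))
})
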