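test_that("elasticity application is the matrix product in percent space", {
  E <- elasticity_matrix(diag(-0.5, 16))
  dp <- rep(10, 16)
  expect_equal(unname(consumption_change_vector(dp, E)), rep(-5, 16))
  expect_equal(unname(consumption_change_vector(rep(0, 16), E)),
               rep(0, 16))
  # one cross term: e[1,2] = +0.2 with +10% on category 2 gives +2% on 1
  m <- matrix(0, 16, 16); m[1, 2] <- 0.2
  E2 <- suppressWarnings(elasticity_matrix(m))
  dp2 <- c(0, 10, rep(0, 14))
  expect_equal(unname(consumption_change_vector(dp2, E2))[1], 2)
  expect_error(consumption_change_vector(rep(1, 5), E), "length 16")
})

test_that("consumption response is additive in price changes", {
  E <- default_elasticities()$moderate
  set.seed(4)
  for (i in 1:20) {
    p1 <- runif(16, -10, 10); p2 <- runif(16, -10, 10)
    expect_equal(consumption_change_vector(p1 + p2, E),
                 consumption_change_vector(p1, E) +
                   consumption_change_vector(p2, E), tolerance = 1e-12)
  }
})

test_that("individual consumption updates follow the share-weighted rule", {
  ind <- assign_subgroups(tiny_population())
  # all-zero change is the identity
  same <- apply_consumption_change(ind, rep(0, 16))
  expect_equal(same$mean_weekly_units, ind$mean_weekly_units)

  # single-category drinker falls exactly 10%
  dc <- rep(0, 16); dc[3] <- -10
  out <- apply_consumption_change(ind, dc)
  expect_equal(out$mean_weekly_units[2], 60 * 0.9)

  # 50/50 drinker with (-10, +10): mean unchanged, shares 45/55
  dc2 <- rep(0, 16); dc2[1] <- -10; dc2[2] <- 10
  out2 <- apply_consumption_change(ind, dc2)
  expect_equal(out2$mean_weekly_units[1], 10)
  expect_equal(unname(unlist(
    out2[1, paste0("share_", beverage_categories()[1:2])])), c(0.45, 0.55))

  # abstainers never change
  expect_equal(out2$mean_weekly_units[4], 0)

  # population ethanol conservation: aggregate change from individuals
  # equals the share-weighted aggregate of category changes (oracle)
  pop <- synth_population(n_per_cell = 25, seed = 17)
  dc3 <- runif(16, -20, 5)
  new <- apply_consumption_change(pop, dc3)
  units_by_cat <- colSums(share_mat <- as.matrix(
    pop[, paste0("share_", beverage_categories())]) *
      pop$mean_weekly_units * pop$weight)
  expected_total <- sum(units_by_cat * (1 + dc3 / 100))
  expect_equal(sum(new$mean_weekly_units * new$weight), expected_total,
               tolerance = 1e-9)
})

test_that("peak updates preserve the residual and clamp at zero", {
  ind <- assign_subgroups(tiny_population())
  bm <- default_population_config()$binge
  # no mean change: peak unchanged
  same <- update_peak(ind, ind$mean_weekly_units, ind$mean_weekly_units, bm)
  expect_equal(same$peak_day_units, ind$peak_day_units)
  # slope 0.5, mean falls 4 -> peak falls 2
  bm2 <- bm; bm2$slope <- 0.5
  out <- update_peak(ind, ind$mean_weekly_units,
                     ind$mean_weekly_units - 4, bm2)
  expect_equal(out$peak_day_units, pmax(ind$peak_day_units - 2, 0))
  # crossing zero clamps
  bm3 <- bm; bm3$slope <- 10
  out3 <- update_peak(ind, ind$mean_weekly_units,
                      pmax(ind$mean_weekly_units - 5, 0), bm3)
  expect_true(all(out3$peak_day_units >= 0))
  # missing cell coefficients are rejected
  expect_error(update_peak(ind, ind$mean_weekly_units,
                           ind$mean_weekly_units, bm[1:3, ]),
               "missing coefficients")
})

test_that("relative consumption changes scale every drinker", {
  ind <- assign_subgroups(tiny_population())
  bm <- default_population_config()$binge
  out <- apply_relative_change(ind, -10, bm)
  expect_equal(out$mean_weekly_units, ind$mean_weekly_units * 0.9)
  idn <- apply_relative_change(ind, 0, bm)
  expect_equal(idn$mean_weekly_units, ind$mean_weekly_units)
  expect_equal(idn$peak_day_units, ind$peak_day_units)
  # weighted mean consumption falls by exactly the stated percent
  pop <- synth_population(n_per_cell = 25, seed = 19)
  down <- apply_relative_change(pop, -26.9, bm)
  expect_equal(sum(down$mean_weekly_units * down$weight),
               sum(pop$mean_weekly_units * pop$weight) * (1 - 0.269),
               tolerance = 1e-12)
})

test_that("elasticity uncertainty sampling reproduces mean and covariance", {
  mu <- c(-0.5, -0.3, 0.1)
  S <- matrix(c(0.04, 0.01, 0, 0.01, 0.09, 0.02, 0, 0.02, 0.05), 3, 3)
  draws <- sample_elasticity_matrices(mu, S, 10000, seed = 6)
  # CLT bound: sample mean within 3 standard errors
  se <- sqrt(diag(S) / 10000)
  expect_true(all(abs(colMeans(draws) - mu) < 3 * se))
  expect_equal(stats::cov(draws), S, tolerance = 0.12)
  # zero covariance: every draw equals the mean
  z <- sample_elasticity_matrices(mu, matrix(0, 3, 3), 5, seed = 1)
  expect_true(all(t(z) == mu))
  # non-PSD covariance rejected
  bad <- matrix(c(1, 2, 2, 1), 2, 2)
  expect_error(sample_elasticity_matrices(c(0, 0), bad, 2),
               "positive semi-definite")
  # reproducible by seed
  expect_identical(sample_elasticity_matrices(mu, S, 5, seed = 9),
                   sample_elasticity_matrices(mu, S, 5, seed = 9))
})

test_that("elasticity matrices round-trip through labelled CSV", {
  E <- default_elasticities()$hazardous_harmful
  f <- withr::local_tempfile(fileext = ".csv")
  write_elasticity_csv(E, f)
  back <- read_elasticity_csv(f, "hazardous_harmful")
  expect_equal(unclass(back), unclass(E), tolerance = 1e-12,
               ignore_attr = TRUE)
})
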