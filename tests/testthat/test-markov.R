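test_that("every transition distribution is a probability distribution", {
  for (arm in c("BIMODAL", "SIMULTANEOUS", "SEQUENTIAL")) {
    for (state in c("DEV1", "DEV2", "DEV3", "DEATH")) {
      for (ctx in list(list(age = 1, years_since_current_device = 1, arm = arm),
                       list(age = 2, years_since_current_device = 1, arm = arm),
                       list(age = 30, years_since_current_device = 12, arm = arm),
                       list(age = 80, years_since_current_device = 40, arm = arm))) {
        d <- transition_distribution(state, ctx, fx_params, fx_lt)
        expect_lt(abs(sum(d$prob) - 1), 1e-12)
        expect_true(all(d$prob >= 0))
      }
    }
  }
})

test_that("death is absorbing and resolved before all other events", {
  d <- transition_distribution("DEATH",
    list(age = 40, years_since_current_device = 5, arm = "BIMODAL"),
    fx_params, fx_lt)
  expect_identical(d$next_state, "DEATH")
  expect_identical(d$prob, 1)
  # died excludes all other flags in the same cycle
  d2 <- transition_distribution("DEV1",
    list(age = 40, years_since_current_device = 5, arm = "BIMODAL"),
    fx_params, fx_lt)
  expect_true(all(!d2$wound[d2$died] & !d2$explant[d2$died] & !d2$failure[d2$died]))
})

test_that("subsequent-year complication rates split half wound, half explant", {
  ctx <- list(age = 6, years_since_current_device = 5, arm = "BIMODAL")
  d <- transition_distribution("DEV1", ctx, fx_params, fx_lt)
  qx <- annual_death_probability(fx_lt, 6)
  expect_equal(d$prob[d$wound] / (1 - qx), 0.0005, tolerance = 1e-12)
  expect_equal(d$prob[d$explant] / (1 - qx), 0.0005, tolerance = 1e-12)
  expect_identical(d$next_state[d$explant], "DEV2")
  expect_identical(d$next_state[d$wound], "DEV1")  # wound never changes state
})

test_that("the third device is terminal: no transit to another device state", {
  for (tsd in c(1, 7, 30)) {
    d <- transition_distribution("DEV3",
      list(age = 50, years_since_current_device = tsd, arm = "SIMULTANEOUS"),
      fx_params, fx_lt)
    expect_identical(sum(d$prob[!d$next_state %in% c("DEV3", "DEATH")]), 0)
    expect_identical(sum(d$prob[d$explant | d$failure]), 0)
  }
})

test_that("sequential arms attribute no events before the second implant", {
  d <- transition_distribution("DEV1",
    list(age = 2, years_since_current_device = 2, arm = "SEQUENTIAL"),
    fx_params, fx_lt)
  expect_identical(sum(d$prob[d$wound | d$explant | d$failure]), 0)
  # from the second implantation age the chain is live with first-year rates
  d2 <- transition_distribution("DEV1",
    list(age = 3, years_since_current_device = 1, arm = "SEQUENTIAL"),
    fx_params, fx_lt)
  qx <- annual_death_probability(fx_lt, 3)
  expect_equal(d2$prob[d2$explant] / (1 - qx), 0.005, tolerance = 1e-12)
})

test_that("utility increments follow the printed age-band cells", {
  expect_equal(utility_increment(60, fx_arm("SIMULTANEOUS"), fx_params$utilities),
               0.227 + 0.0294)
  # second implant not yet placed at age 2 in the sequential arm
  expect_equal(utility_increment(2, fx_arm("SEQUENTIAL"), fx_params$utilities),
               0.212)
  expect_equal(utility_increment(3, fx_arm("SEQUENTIAL"), fx_params$utilities),
               0.212 + 0.027)
  expect_equal(utility_increment(82, fx_arm("BIMODAL"), fx_params$utilities),
               0.167)
  expect_error(utility_increment(85, fx_arm("BIMODAL"), fx_params$utilities),
               "outside all utility age bands")
})

test_that("overridden utility bases switch the cells to scaling x base", {
  p <- apply_override(fx_params, "utilities.base_increment_bilateral_extra", 0.06)
  u <- utility_increment(1, p$strategies$SIMULTANEOUS, p$utilities)
  expect_equal(u, 0.066 + 0.28 * 0.06)  # bimodal cell printed, extra derived
  p0 <- apply_override(fx_params, "utilities.base_increment_bimodal", 0)
  p0 <- apply_override(p0, "utilities.base_increment_bilateral_extra", 0)
  expect_equal(utility_increment(30, p0$strategies$SIMULTANEOUS, p0$utilities), 0)
})

test_that("discounting: costs from cycle start, QALYs from mid-cycle", {
  expect_identical(discount_factor(0, 17), 1)
  expect_identical(discount_factor(0.03, 1), 1)  # first-year costs undiscounted
  expect_equal(discount_factor(0.03, 1, mid_cycle = TRUE), 1.03^-0.5)
  expect_equal(discount_factor(0.03, 10), 1.03^-9)
})

test_that("cohort occupancy is a probability vector every cycle", {
  for (arm in c("BIMODAL", "SEQUENTIAL")) {
    tr <- run_cohort(fx_params, arm, fx_lt)
    occ <- tr$cycles[, c("occ_dev1", "occ_dev2", "occ_dev3", "occ_death")]
    expect_true(all(occ >= -1e-15 & occ <= 1 + 1e-15))
    expect_true(all(abs(rowSums(occ) - 1) < 1e-12))
    # totals equal the per-cycle sums
    expect_equal(tr$totals$discounted_qaly, sum(tr$cycles$qaly_disc),
                 tolerance = 1e-9)
    expect_equal(tr$totals$discounted_cost,
                 sum(tr$cycles$cost_scheduled_disc) + sum(tr$cycles$cost_event_disc),
                 tolerance = 1e-9)
  }
})

test_that("zeroed utility increments give exactly zero QALYs", {
  p <- apply_override(fx_params, "utilities.base_increment_bimodal", 0)
  p <- apply_override(p, "utilities.base_increment_bilateral_extra", 0)
  tr <- run_cohort(p, "SIMULTANEOUS", fx_lt)
  expect_identical(tr$totals$discounted_qaly, 0)
})

test_that("discounting lowers accumulated QALYs", {
  q0 <- run_cohort(apply_override(fx_params, "economic.discount_rate_annual", 0),
                   "BIMODAL", fx_lt)$totals$discounted_qaly
  q3 <- run_cohort(fx_params, "BIMODAL", fx_lt)$totals$discounted_qaly
  expect_gt(q0, q3)
})

test_that("the device clock resets on replacement (trace inspection)", {
  # craft a reliability model that spares year 1 and kills every device in
  # its second year; with events and mortality off, the cohort must sit in
  # DEV1 for cycles 1-2, DEV2 for cycles 3-4, then DEV3 for good
  p <- eventless_params()
  crv <- reliability_curve(1:3, c(1, 1e-9, 1e-9))
  p$reliability <- linear_survival_model(intercept = 0.5, slope_per_year = 0,
                                         valid_from_year = 4, points = crv)
  tr <- run_cohort(p, "BIMODAL", flat_life_table())
  occ <- tr$cycles
  expect_equal(occ$occ_dev1[1:2], c(1, 1), tolerance = 1e-6)
  expect_equal(occ$occ_dev2[3:4], c(1, 1), tolerance = 1e-6)
  expect_equal(occ$occ_dev3[5:10], rep(1, 6), tolerance = 1e-6)
  # and the cap holds forever after
  expect_equal(occ$occ_dev3[nrow(occ)], 1, tolerance = 1e-6)
})

test_that("microsimulation is reproducible and respects the replacement cap", {
  a <- run_microsim(fx_params, "SIMULTANEOUS", fx_lt, n = 2000, seed = 11)
  b <- run_microsim(fx_params, "SIMULTANEOUS", fx_lt, n = 2000, seed = 11)
  expect_identical(a, b)
  # inflate event rates so replacements would exceed the cap if uncapped
  p <- fx_params
  p$clinical$p_major_first_year <- 0.4
  p$clinical$p_wound_first_year <- 0.2
  p$clinical$p_explant_first_year <- 0.2
  p$clinical$p_major_subsequent <- 0.4
  p$clinical$p_wound_subsequent <- 0.2
  p$clinical$p_explant_subsequent <- 0.2
  ms <- run_microsim(p, "SIMULTANEOUS", fx_lt, n = 3000, seed = 5)
  expect_lte(ms$max_replacements, 2)
  expect_gt(ms$max_replacements, 0)
})

test_that("with all randomness removed the microsim equals the closed sum", {
  p <- eventless_params()
  ms <- run_microsim(p, "BIMODAL", flat_life_table(), n = 1, seed = 1)
  # deterministic discounted utility sum, written out independently
  cells <- c(0.066, rep(0.212, 2), rep(0.232, 51), rep(0.227, 10),
             rep(0.223, 5), rep(0.211, 5), rep(0.195, 5), rep(0.167, 5))
  expected <- sum(cells * 1.03^-(seq_along(cells) - 0.5))
  expect_equal(ms$discounted_qaly, expected, tolerance = 1e-12)
})
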