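test_that("incremental scheduled costs reproduce the published table sums", {
  # sequential, year of the second implantation: device + surgery + ward day
  # + first-year habilitation block
  expect_equal(
    scheduled_cycle_cost(fx_params, "SEQUENTIAL", 3, include_backbone = FALSE),
    28216 + 4940 + 172 + 10 * 81 + 2 * 53 + 52 * 116 + 2 * 57 + 2 * 35)  # 40,460
  # sequential, pre-surgery assessment year
  expect_equal(
    scheduled_cycle_cost(fx_params, "SEQUENTIAL", 2, include_backbone = FALSE),
    4 * 81 + 4 * 53 + 6 * 116 + 2 * 57 + 1 * 35 + 1 * 405)  # 1,786
  # simultaneous: nothing incremental is scheduled in year 6
  expect_identical(
    scheduled_cycle_cost(fx_params, "SIMULTANEOUS", 6, include_backbone = FALSE), 0)
  # hearing-aid replacement fires on the bimodal arm every 5 years
  expect_equal(
    scheduled_cycle_cost(fx_params, "BIMODAL", 5, include_backbone = FALSE), 949)
  expect_identical(
    scheduled_cycle_cost(fx_params, "BIMODAL", 4, include_backbone = FALSE), 0)
})

test_that("unknown schedule resources are configuration errors", {
  p <- fx_params
  p$resource_schedule$scheduled$resource[1] <- "not_a_resource"
  expect_error(scheduled_cycle_cost(p, "BIMODAL", 1), "not_a_resource")
})

test_that("event costs compose surgery, ward day, warranty and doubling", {
  costs <- fx_params$costs
  bim <- list(arm = fx_arm("BIMODAL"), years_since_current_device = 5)
  sim12 <- list(arm = fx_arm("SIMULTANEOUS"), years_since_current_device = 12)
  expect_equal(event_cost(list(wound = TRUE), bim, costs), 6454 + 172)  # 6,626
  # post-warranty failure in a bilateral arm: device charged, cost doubled
  expect_equal(event_cost(list(failure = TRUE), sim12, costs),
               (7115 + 172 + 28216) * 2)  # 71,006
  # within warranty the replacement device is free
  sim5 <- list(arm = fx_arm("SIMULTANEOUS"), years_since_current_device = 5)
  expect_equal(event_cost(list(explant = TRUE), sim5, costs), (7115 + 172) * 2)
  expect_identical(event_cost(list(), bim, costs), 0)
})

test_that("bilateral event-cost streams are exactly twice the bimodal stream", {
  bim <- run_cohort(fx_params, "BIMODAL", fx_lt)
  sim <- run_cohort(fx_params, "SIMULTANEOUS", fx_lt)
  expect_equal(sim$cycles$cost_event_disc, 2 * bim$cycles$cost_event_disc,
               tolerance = 1e-12)
})

test_that("arm totals equal the discounted per-cycle sums", {
  tr <- run_cohort(fx_params, "SEQUENTIAL", fx_lt)
  expect_equal(arm_total_cost(tr), tr$totals$discounted_cost, tolerance = 1e-9)
  p0 <- fx_params
  for (f in bicea:::.money_fields) p0$costs[[f]] <- 0
  expect_identical(run_cohort(p0, "SEQUENTIAL", fx_lt)$totals$discounted_cost, 0)
})

test_that("cost totals decompose exactly into resource units x unit costs", {
  costvec <- unlist(fx_params$costs[bicea:::.money_fields])
  for (arm in c("BIMODAL", "SIMULTANEOUS", "SEQUENTIAL")) {
    tr <- run_cohort(fx_params, arm, fx_lt)
    expect_equal(sum(tr$resource_units * costvec), tr$totals$discounted_cost,
                 tolerance = 1e-9)
  }
})

test_that("incremental results are invariant to backbone perturbations", {
  inc <- function(p) {
    s <- run_cohort(p, "SIMULTANEOUS", fx_lt)$totals
    b <- run_cohort(p, "BIMODAL", fx_lt)$totals
    c(cost = s$discounted_cost - b$discounted_cost,
      qaly = s$discounted_qaly - b$discounted_qaly)
  }
  base <- inc(fx_params)
  p <- fx_params
  all_rows <- p$resource_schedule$scheduled$arm == "ALL"
  p$resource_schedule$scheduled$units[all_rows] <-
    p$resource_schedule$scheduled$units[all_rows] + 4
  p$resource_schedule$scheduled <- rbind(
    p$resource_schedule$scheduled,
    data.frame(arm = "ALL", model_year = 9, resource = "ct_scan",
               units = 2, category = "habilitation"))
  perturbed <- inc(p)
  expect_equal(perturbed, base, tolerance = 1e-9)
  # while arm-level totals of course move
  expect_gt(run_cohort(p, "BIMODAL", fx_lt)$totals$discounted_cost,
            run_cohort(fx_params, "BIMODAL", fx_lt)$totals$discounted_cost)
})

test_that("the published dominance geometry holds on the packaged inputs", {
  bim <- run_cohort(fx_params, "BIMODAL", fx_lt)$totals
  sim <- run_cohort(fx_params, "SIMULTANEOUS", fx_lt)$totals
  sq <- run_cohort(fx_params, "SEQUENTIAL", fx_lt)$totals
  expect_gt(sq$discounted_cost - bim$discounted_cost,
            sim$discounted_cost - bim$discounted_cost)
  expect_lt(sq$discounted_qaly - bim$discounted_qaly,
            sim$discounted_qaly - bim$discounted_qaly)
})

test_that("processor-cost calibration solves the incremental-cost equation", {
  # at the calibrated fixture value the simultaneous increment hits the
  # target; doubling the processor cost overshoots it
  sim <- run_cohort(fx_params, "SIMULTANEOUS", fx_lt)$totals
  bim <- run_cohort(fx_params, "BIMODAL", fx_lt)$totals
  expect_equal(sim$discounted_cost - bim$discounted_cost, 53451,
               tolerance = 1e-4)
  p2 <- apply_override(fx_params, "costs.external_processor_replacement",
                       2 * fx_params$costs$external_processor_replacement)
  sim2 <- run_cohort(p2, "SIMULTANEOUS", fx_lt)$totals
  bim2 <- run_cohort(p2, "BIMODAL", fx_lt)$totals
  expect_gt(sim2$discounted_cost - bim2$discounted_cost, 53451)
})
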