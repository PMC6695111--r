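mk_res <- function(cost, qaly, arm = "X") {
  structure(list(arm = arm, discounted_cost = cost, discounted_qaly = qaly,
                 n = "cohort", standard_errors = NULL), class = "arm_result")
}

test_that("ICERs divide incremental cost by incremental effectiveness", {
  ic <- compute_icer(mk_res(81260, 6.82), mk_res(81260 + 53451, 6.82 + 0.88))
  expect_equal(ic$icer, 53451 / 0.88, tolerance = 1e-12)  # 60,739.8
  expect_identical(ic$dominance, "NONE")
  ic2 <- compute_icer(mk_res(81260, 6.82), mk_res(81260 + 67533, 6.82 + 0.83))
  expect_equal(ic2$icer, 67533 / 0.83, tolerance = 1e-12)  # 81,364
})

test_that("dominance replaces the ICER when the signs oppose", {
  dom <- compute_icer(mk_res(100, 1), mk_res(90, 1.5))
  expect_identical(dom$dominance, "INTERVENTION_DOMINANT")
  expect_true(is.na(dom$icer))
  ded <- compute_icer(mk_res(100, 1), mk_res(150, 0.5))
  expect_identical(ded$dominance, "INTERVENTION_DOMINATED")
  expect_true(is.na(ded$icer))
  undef <- compute_icer(mk_res(100, 1), mk_res(150, 1))
  expect_true(is.na(undef$icer))
  expect_identical(undef$dominance, "NONE")
})

test_that("the tornado is sorted by bar width and behaves monotonically", {
  plan <- data.frame(
    parameter_path = c("costs.initial_implant_cost_multiplier",
                       "costs.hearing_aid",
                       "costs.ci_device"),
    low = c(0.9, 949, 28216),
    high = c(1.1, 949 * 1.1, 28216))  # last entry: low = high = base
  tor <- one_way_dsa(fx_params, plan, c("BIMODAL", "SIMULTANEOUS"), fx_lt)
  expect_true(all(diff(tor$bar_width) <= 0))
  expect_identical(tor$bar_width[tor$parameter_path == "costs.ci_device"], 0)
  # raising the bilateral acquisition cost raises the ICER
  row <- tor[tor$parameter_path == "costs.initial_implant_cost_multiplier", ]
  base <- attr(tor, "base_icer")
  expect_gt(row$icer_at_high, base)
  expect_lt(row$icer_at_low, base)
})

test_that("utility gain and device cost carry the widest tornado bars", {
  tor <- one_way_dsa(fx_params, lt = fx_lt)
  expect_identical(tor$parameter_path[1], "utilities.base_increment_bilateral_extra")
  expect_identical(tor$parameter_path[2], "costs.initial_implant_cost_multiplier")
})

test_that("PSA draws have the method-of-moments gamma/beta shapes", {
  set.seed(99)
  d <- bicea:::.draw_gamma(10000, 28216, 1)  # shape 1, scale 28216
  expect_equal(mean(d), 28216, tolerance = 0.03)
  expect_equal(stats::sd(d), 28216, tolerance = 0.05)
  u <- bicea:::.draw_beta(10000, 0.03, 1)
  expect_equal(mean(u), 0.03, tolerance = 0.03)
  expect_equal(stats::sd(u), 0.03, tolerance = 0.05)
  expect_true(all(u > 0 & u < 1))
  # infeasible beta moments are truncated with a warning
  expect_warning(bicea:::.draw_beta(10, 0.6, 1), "truncated")
})

test_that("degenerate CV reproduces the base case draw for draw", {
  p <- fx_params
  p$psa$cv_costs <- 0
  p$psa$cv_utilities <- 0
  ov <- sample_psa_parameters(p, seed = 3)
  expect_identical(ov[["costs.ci_device"]], 28216)
  expect_identical(ov[["utilities.base_increment_bilateral_extra"]], 0.03)
  psa <- run_psa(p, fx_lt, n_draws = 2, seed = 3)
  base <- run_cohort(p, "SEQUENTIAL", fx_lt)$totals
  expect_equal(psa$draws$cost_SEQUENTIAL, rep(base$discounted_cost, 2),
               tolerance = 1e-12)
  expect_equal(psa$draws$qaly_SEQUENTIAL, rep(base$discounted_qaly, 2),
               tolerance = 1e-12)
})

test_that("PSA is seed-reproducible", {
  a <- run_psa(fx_params, fx_lt, n_draws = 50, seed = 7)
  b <- run_psa(fx_params, fx_lt, n_draws = 50, seed = 7)
  expect_identical(a$draws, b$draws)
})

test_that("linearised PSA evaluation equals a full cohort rerun of the draw", {
  psa <- run_psa(fx_params, fx_lt, n_draws = 8, seed = 17)
  row <- psa$draws[5, ]
  p2 <- fx_params
  for (nm in grep("^(costs|utilities)\\.", names(psa$draws), value = TRUE)) {
    p2 <- apply_override(p2, nm, row[[nm]])
  }
  for (arm in c("BIMODAL", "SIMULTANEOUS", "SEQUENTIAL")) {
    tr <- run_cohort(p2, arm, fx_lt)$totals
    expect_equal(row[[paste0("cost_", arm)]], tr$discounted_cost,
                 tolerance = 1e-9)
    expect_equal(row[[paste0("qaly_", arm)]], tr$discounted_qaly,
                 tolerance = 1e-9)
  }
})

test_that("CEAC rows partition probability and favour cheap options at WTP 0", {
  psa <- run_psa(fx_params, fx_lt, n_draws = 400, seed = 21)
  cc <- ceac(psa, wtp_grid = c(0, 30000, 61000, 100000))
  probs <- as.matrix(cc[, psa$arms])
  expect_true(all(abs(rowSums(probs) - 1) < 1e-9))
  # at WTP 0 the net-benefit ranking is by cost alone
  expect_gt(cc$BIMODAL[cc$wtp == 0], 0.95)
})
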