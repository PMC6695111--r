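# Economic analysis: incremental cost-effectiveness ratios with dominance
# handling, one-way deterministic sensitivity analysis (tornado), second-order
# probabilistic sensitivity analysis, and cost-effectiveness acceptability
# curves.

.result_of <- function(x) {
  if (inherits(x, "cea_trace")) x$totals else x
}

#' Incremental cost-effectiveness ratio with dominance flags
#'
#' `delta = intervention - control`. When the signs oppose, the comparison is
#' settled by dominance (cheaper and more effective, or costlier and less
#' effective) and no ICER is reported; the ICER is defined only when both
#' deltas share a sign and the QALY delta is nonzero.
#'
#' @param control,intervention `arm_result`s (or `cea_trace`s) from the same
#'   parameters and life table.
#' @return An `icer_result`: list with `delta_cost`, `delta_qaly`, `icer`
#'   (`NA` when undefined), `dominance` (one of `"NONE"`,
#'   `"INTERVENTION_DOMINANT"`, `"INTERVENTION_DOMINATED"`), and the arm
#'   labels.
#' @export
compute_icer <- function(control, intervention) {
  ctl <- .result_of(control)
  int <- .result_of(intervention)
  dc <- int$discounted_cost - ctl$discounted_cost
  dq <- int$discounted_qaly - ctl$discounted_qaly
  dominance <- "NONE"
  icer <- NA_real_
  if (dc < 0 && dq > 0) {
    dominance <- "INTERVENTION_DOMINANT"
  } else if (dc > 0 && dq < 0) {
    dominance <- "INTERVENTION_DOMINATED"
  } else if (dq != 0) {
    icer <- dc / dq
  }
  structure(list(control = ctl$arm, intervention = int$arm,
                 delta_cost = dc, delta_qaly = dq,
                 icer = icer, dominance = dominance),
            class = "icer_result")
}

#' @export
print.icer_result <- function(x, ...) {
  cat(sprintf("%s vs %s: delta cost %s USD, delta QALY %.4f\n",
              x$intervention, x$control,
              format(round(x$delta_cost), big.mark = ","), x$delta_qaly))
  if (x$dominance != "NONE") {
    cat("  ", x$dominance, " (no ICER)\n", sep = "")
  } else if (is.na(x$icer)) {
    cat("  ICER undefined (zero QALY difference)\n")
  } else {
    cat(sprintf("  ICER: %s USD/QALY\n", format(round(x$icer), big.mark = ",")))
  }
  invisible(x)
}

#' Default one-way sensitivity-analysis plan
#'
#' The five published tornado parameters: the bilateral utility increment
#' (halved, and raised to the alternative literature value 0.06), the
#' acquisition cost of the initial bilateral implantation (both implant
#' systems plus surgery, varied via its multiplier by +/-10%), and +/-10% on
#' the hearing-aid, implantation-surgery and re-implantation unit costs.
#'
#' @param params A `cea_parameters` object (supplies the base values).
#' @return Data frame with columns `parameter_path`, `low`, `high`.
#' @export
default_dsa_plan <- function(params) {
  cs <- params$costs
  data.frame(
    parameter_path = c("utilities.base_increment_bilateral_extra",
                       "costs.initial_implant_cost_multiplier",
                       "costs.hearing_aid",
                       "costs.surgery_implantation",
                       "costs.surgery_explant_reimplant"),
    low = c(0.015, 0.9, 0.9 * cs$hearing_aid, 0.9 * cs$surgery_implantation,
            0.9 * cs$surgery_explant_reimplant),
    high = c(0.06, 1.1, 1.1 * cs$hearing_aid, 1.1 * cs$surgery_implantation,
             1.1 * cs$surgery_explant_reimplant)
  )
}

#' One-way deterministic sensitivity analysis (tornado)
#'
#' Reruns the cohort model for one strategy pair with each plan parameter set
#' to its low and high value, all else held at base, and returns the entries
#' sorted by descending ICER bar width (tornado ordering).
#'
#' @param params A `cea_parameters` object.
#' @param plan Data frame of (`parameter_path`, `low`, `high`); defaults to
#'   [default_dsa_plan()].
#' @param pair Character vector `c(control, intervention)`.
#' @param lt A `life_table`.
#' @return A `cea_dsa`: data frame with per-parameter low/high ICERs and bar
#'   widths, with the base-case ICER as attribute `base_icer`.
#' @export
one_way_dsa <- function(params, plan = default_dsa_plan(params),
                        pair = c("BIMODAL", "SIMULTANEOUS"), lt) {
  icer_at <- function(p) {
    compute_icer(run_cohort(p, pair[1], lt), run_cohort(p, pair[2], lt))$icer
  }
  base_icer <- icer_at(params)
  rows <- lapply(seq_len(nrow(plan)), function(i) {
    lo <- icer_at(apply_override(params, plan$parameter_path[i], plan$low[i]))
    hi <- icer_at(apply_override(params, plan$parameter_path[i], plan$high[i]))
    data.frame(parameter_path = plan$parameter_path[i],
               low_value = plan$low[i], high_value = plan$high[i],
               icer_at_low = lo, icer_at_high = hi,
               bar_width = abs(hi - lo))
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$bar_width), ]
  rownames(out) <- NULL
  attr(out, "base_icer") <- base_icer
  attr(out, "pair") <- pair
  class(out) <- c("cea_dsa", "data.frame")
  out
}

#' Plot a tornado diagram
#'
#' @param x A `cea_dsa`.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.cea_dsa <- function(x, ...) {
  base <- attr(x, "base_icer")
  o <- x[rev(seq_len(nrow(x))), ]
  graphics::barplot(
    rbind(o$icer_at_low - base, o$icer_at_high - base),
    beside = FALSE, horiz = TRUE, names.arg = o$parameter_path,
    offset = base, las = 1, xlab = "ICER (USD/QALY)",
    main = paste(attr(x, "pair")[2], "vs", attr(x, "pair")[1]), ...)
  graphics::abline(v = base, lty = 2)
  invisible(x)
}

# Gamma and beta method-of-moments draws with the configured coefficient of
# variation. The published rule sets each parameter's standard deviation to
# its mean (CV = 1); infeasible beta moments are truncated to 95% of the
# feasible bound with a warning.
.draw_gamma <- function(n, mean, cv) {
  if (cv == 0 || mean == 0) return(rep(mean, n))
  shape <- 1 / cv^2
  stats::rgamma(n, shape = shape, scale = mean * cv^2)
}

.draw_beta <- function(n, mean, cv, label = "utility") {
  if (cv == 0) return(rep(mean, n))
  s <- cv * mean
  s_max <- sqrt(mean * (1 - mean))
  if (s >= s_max) {
    warning(sprintf("beta SD %.4g for %s infeasible (mean %.4g); truncated to %.4g",
                    s, label, mean, 0.95 * s_max), call. = FALSE)
    s <- 0.95 * s_max
  }
  nu <- mean * (1 - mean) / s^2 - 1
  stats::rbeta(n, shape1 = mean * nu, shape2 = (1 - mean) * nu)
}

# Canonical sampling order: the money fields, then the two utility bases.
# Fixing the order makes the draw stream reproducible across functions.
.psa_sampled_paths <- function() {
  c(paste0("costs.", .money_fields),
    "utilities.base_increment_bimodal", "utilities.base_increment_bilateral_extra")
}

.psa_draw_matrix <- function(params, n) {
  cvc <- params$psa$cv_costs
  cvu <- params$psa$cv_utilities
  cols <- lapply(.money_fields, function(f) .draw_gamma(n, params$costs[[f]], cvc))
  names(cols) <- paste0("costs.", .money_fields)
  cols[["utilities.base_increment_bimodal"]] <-
    .draw_beta(n, params$utilities$base_increment_bimodal, cvu,
               "base_increment_bimodal")
  cols[["utilities.base_increment_bilateral_extra"]] <-
    .draw_beta(n, params$utilities$base_increment_bilateral_extra, cvu,
               "base_increment_bilateral_extra")
  do.call(cbind, cols)
}

#' Sample one probabilistic-sensitivity-analysis parameter set
#'
#' Each cost draws from a gamma and each utility base increment from a beta
#' distribution, parameterised by method of moments with mean equal to the
#' base value and SD equal to `CV x mean` (`params$psa$cv_costs`,
#' `params$psa$cv_utilities`; the published rule is CV = 1). Transition
#' probabilities are held fixed.
#'
#' @param params A `cea_parameters` object.
#' @param seed Integer seed.
#' @return Named list of overrides (dotted path -> sampled value), applicable
#'   via [apply_override()].
#' @export
sample_psa_parameters <- function(params, seed) {
  set.seed(seed)
  m <- .psa_draw_matrix(params, 1)
  as.list(m[1, ])
}

#' Second-order probabilistic sensitivity analysis
#'
#' Samples `n_draws` parameter sets and evaluates the three strategies in
#' cohort mode for each (first-order variability integrated out). Cohort
#' arm results are exactly linear in the unit costs and the two utility base
#' increments, so each draw is evaluated through the discounted resource-unit
#' and utility-exposure decomposition of one base cohort run per arm; this is
#' exact, not an approximation, and is verified against full reruns in the
#' test suite.
#'
#' @param params A `cea_parameters` object.
#' @param lt A `life_table`.
#' @param n_draws Number of second-order draws (the published analysis used
#'   10,000).
#' @param seed Integer seed; same seed, same draws.
#' @param arms Strategies to evaluate.
#' @return A `cea_psa`: list with `draws` (one row per draw: sampled
#'   parameters and each arm's discounted cost and QALY), `base` (base-case
#'   arm results), `n_draws`, `seed`.
#' @export
run_psa <- function(params, lt, n_draws = 10000, seed = 1L,
                    arms = c("BIMODAL", "SIMULTANEOUS", "SEQUENTIAL")) {
  stopifnot(n_draws >= 1)
  traces <- lapply(arms, function(a) run_cohort(params, a, lt))
  names(traces) <- arms
  set.seed(seed)
  draws <- .psa_draw_matrix(params, n_draws)
  cost_cols <- paste0("costs.", .money_fields)
  basis_b <- params$utilities$printed_basis_bimodal
  basis_x <- params$utilities$printed_basis_bilateral
  out <- data.frame(draw = seq_len(n_draws))
  for (a in arms) {
    tr <- traces[[a]]
    cost <- as.numeric(draws[, cost_cols, drop = FALSE] %*% tr$resource_units)
    bb <- draws[, "utilities.base_increment_bimodal"]
    bx <- draws[, "utilities.base_increment_bilateral_extra"]
    # cell rule: draws exactly at the printed basis reproduce the printed
    # cells (relevant when CV = 0), otherwise cells are scaling x base
    qaly <- ifelse(bb == basis_b, tr$utility_exposure["printed_bimodal"],
                   bb * tr$utility_exposure["scaled_bimodal"]) +
            ifelse(bx == basis_x, tr$utility_exposure["printed_extra"],
                   bx * tr$utility_exposure["scaled_extra"])
    out[[paste0("cost_", a)]] <- cost
    out[[paste0("qaly_", a)]] <- qaly
  }
  out <- cbind(out, as.data.frame(draws))
  structure(list(draws = out, base = lapply(traces, function(t) t$totals),
                 arms = arms, n_draws = n_draws, seed = seed),
            class = "cea_psa")
}

#' @export
print.cea_psa <- function(x, ...) {
  cat(sprintf("PSA: %d second-order draws, arms %s\n", x$n_draws,
              paste(x$arms, collapse = ", ")))
  for (a in x$arms) {
    cat(sprintf("  %s: mean cost %s, mean QALY %.3f\n", a,
                format(round(mean(x$draws[[paste0("cost_", a)]])), big.mark = ","),
                mean(x$draws[[paste0("qaly_", a)]])))
  }
  invisible(x)
}

#' Cost-effectiveness acceptability curves
#'
#' For each willingness-to-pay threshold, the probability that each strategy
#' is cost-effective is the fraction of draws in which its net monetary
#' benefit (`wtp x QALY - cost`) is strictly highest; exact ties split their
#' weight equally. Each row's probabilities sum to 1.
#'
#' @param psa A `cea_psa` from [run_psa()].
#' @param wtp_grid Willingness-to-pay thresholds (USD/QALY).
#' @return A `cea_ceac`: data frame with column `wtp` and one probability
#'   column per strategy.
#' @export
ceac <- function(psa, wtp_grid = seq(0, 100000, by = 2000)) {
  stopifnot(inherits(psa, "cea_psa"), psa$n_draws >= 1)
  arms <- psa$arms
  qal <- as.matrix(psa$draws[paste0("qaly_", arms)])
  cst <- as.matrix(psa$draws[paste0("cost_", arms)])
  rows <- lapply(wtp_grid, function(w) {
    nmb <- w * qal - cst
    best <- nmb == apply(nmb, 1, max)
    wt <- best / rowSums(best)  # ties split equally
    stats::setNames(as.data.frame(t(colMeans(wt))), arms)
  })
  out <- cbind(wtp = wtp_grid, do.call(rbind, rows))
  rownames(out) <- NULL
  class(out) <- c("cea_ceac", "data.frame")
  out
}

#' Plot cost-effectiveness acceptability curves
#'
#' @param x A `cea_ceac`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.cea_ceac <- function(x, ...) {
  arms <- setdiff(names(x), "wtp")
  graphics::matplot(x$wtp, as.matrix(x[arms]), type = "l", lty = 1,
                    xlab = "Willingness to pay (USD/QALY)",
                    ylab = "Probability cost-effective", ylim = c(0, 1), ...)
  graphics::legend("right", legend = arms, lty = 1,
                   col = seq_along(arms), bty = "n")
  invisible(x)
}
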