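# The four-state Markov engine: "use of 1st internal device" (DEV1),
# "use of 2nd internal device" (DEV2), "use of 3rd internal device" (DEV3)
# and "death" (DEATH, absorbing), over annual cycles from the start age to
# the horizon.
#
# Competing risks are resolved in a fixed order within each cycle: all-cause
# death first (life-table qx), then a major complication (first-year vs
# subsequent rate on the clock "years since the current device's
# implantation", split half wound revision / half explantation), then
# internal-device failure at the reliability hazard on the same clock,
# conditional on no complication. Explantation and failure advance
# DEV1 -> DEV2 -> DEV3 and reset the clock; wound revision never changes
# state. In DEV3 the replacement cap is reached: further explant/failure
# events are suppressed (wound revision can still occur). In the sequential
# arm no events are attributed to the first implant, so the event chain
# starts at the second implantation age; before it, only mortality applies.
#
# The engine tracks one device chain per patient and doubles replacement
# costs in bilateral arms, mirroring the published model, rather than
# simulating two ears independently.

.states <- c("DEV1", "DEV2", "DEV3", "DEATH")

#' Discount factor for one cycle
#'
#' Costs are discounted from the cycle start, `(1+rate)^-(cycle-1)`; QALYs
#' carry the half-cycle correction and are discounted from mid-cycle,
#' `(1+rate)^-(cycle-0.5)`. First-year costs are therefore undiscounted.
#'
#' @param rate Annual discount rate (fraction, `>= 0`).
#' @param cycle_index Cycle number, `>= 1`; vectorised.
#' @param mid_cycle `TRUE` for the QALY (mid-cycle) factor.
#' @return Discount factor(s).
#' @export
discount_factor <- function(rate, cycle_index, mid_cycle = FALSE) {
  stopifnot(rate >= 0, all(cycle_index >= 1))
  (1 + rate)^(-(cycle_index - 1 + if (mid_cycle) 0.5 else 0))
}

# Per-band utility cells under the cell rule: the literal printed table cells
# whenever the base increment equals the printed basis, otherwise
# scaling x base (the printed cells embed the source tables' own rounding,
# so recomputed products differ in the last decimal).
.utility_cells <- function(us) {
  ab <- us$age_bands
  bim <- if (identical(us$base_increment_bimodal, us$printed_basis_bimodal)) {
    ab$printed_bimodal
  } else {
    ab$scaling * us$base_increment_bimodal
  }
  bil <- if (identical(us$base_increment_bilateral_extra, us$printed_basis_bilateral)) {
    ab$printed_bilateral
  } else {
    ab$scaling * us$base_increment_bilateral_extra
  }
  data.frame(age_low = ab$age_low, age_high = ab$age_high,
             bimodal = bim, bilateral_extra = bil)
}

.band_index <- function(us, age) {
  ab <- us$age_bands
  idx <- vapply(age, function(a) {
    w <- which(a >= ab$age_low & a <= ab$age_high)
    if (length(w) != 1L) NA_integer_ else w
  }, integer(1))
  if (anyNA(idx)) {
    stop("age ", age[which(is.na(idx))[1]], " outside all utility age bands (",
         min(ab$age_low), "-", max(ab$age_high), ")", call. = FALSE)
  }
  idx
}

#' Annual utility increment for an arm at a given age
#'
#' QALYs accrue on the gain-over-no-implantation scale (the no-implant
#' baseline is normalised to 0). Every arm receives the bimodal gain for the
#' age's band; bilateral arms add the bilateral-over-bimodal gain from the
#' second implant's implantation age onward. Death contributes 0.
#'
#' @param age Age in whole years; vectorised.
#' @param arm Strategy definition (see [default_parameters()]).
#' @param us The `utilities` element of a `cea_parameters` object.
#' @return Utility increment(s) per year.
#' @export
utility_increment <- function(age, arm, us) {
  cells <- .utility_cells(us)
  idx <- .band_index(us, age)
  u <- cells$bimodal[idx]
  if (.is_bilateral(arm)) {
    u <- u + ifelse(age >= arm$age_second_implant, cells$bilateral_extra[idx], 0)
  }
  u
}

# Conditional-on-survival event probabilities for one occupied cell of the
# chain. Shared by the cohort engine, the microsimulation and
# transition_distribution so all three see identical rates.
.event_rates <- function(clinical, reliability, tsd, dev) {
  first <- tsd == 1
  p_w <- ifelse(first, clinical$p_wound_first_year, clinical$p_wound_subsequent)
  p_e <- ifelse(first, clinical$p_explant_first_year, clinical$p_explant_subsequent)
  q_f <- annual_failure_probability(reliability, tsd)
  p_f <- (1 - p_w - p_e) * q_f
  if (dev >= 3) {  # replacement cap: no further device advancement
    p_e <- 0
    p_f <- 0
  }
  list(wound = p_w, explant = p_e, failure = p_f)
}

#' One-cycle transition distribution from a health state
#'
#' Returns the full distribution over (next state, cycle events) for one
#' cycle, with competing risks resolved death-first as described in the
#' engine documentation. Probabilities sum to 1.
#'
#' @param state One of `"DEV1"`, `"DEV2"`, `"DEV3"`, `"DEATH"`.
#' @param ctx Cycle context: list with `age`, `years_since_current_device`,
#'   and `arm` (strategy definition).
#' @param params A `cea_parameters` object.
#' @param lt A `life_table`.
#' @return Data frame with columns `next_state`, `died`, `wound`, `explant`,
#'   `failure`, `prob`.
#' @export
transition_distribution <- function(state, ctx, params, lt) {
  stopifnot(state %in% .states)
  arm <- .resolve_strategy(params, ctx$arm)
  out <- function(next_state, died, wound, explant, failure, prob) {
    data.frame(next_state = next_state, died = died, wound = wound,
               explant = explant, failure = failure, prob = prob)
  }
  if (state == "DEATH") {
    return(out("DEATH", FALSE, FALSE, FALSE, FALSE, 1))
  }
  qx <- annual_death_probability(lt, ctx$age)
  chain_start <- if (identical(arm$arm, "SEQUENTIAL")) {
    arm$age_second_implant
  } else {
    arm$age_first_implant
  }
  if (ctx$age < chain_start) {
    # event chain not yet active (sequential arm before the second implant):
    # mortality only
    res <- out(c("DEATH", state), c(TRUE, FALSE), FALSE, FALSE, FALSE,
               c(qx, 1 - qx))
    return(res[res$prob > 0 | res$next_state == state, ])
  }
  dev <- match(state, .states)
  r <- .event_rates(params$clinical, params$reliability,
                    ctx$years_since_current_device, dev)
  adv <- .states[min(dev + 1L, 3L)]
  res <- out(
    next_state = c("DEATH", state, adv, adv, state),
    died = c(TRUE, FALSE, FALSE, FALSE, FALSE),
    wound = c(FALSE, TRUE, FALSE, FALSE, FALSE),
    explant = c(FALSE, FALSE, TRUE, FALSE, FALSE),
    failure = c(FALSE, FALSE, FALSE, TRUE, FALSE),
    prob = c(qx,
             (1 - qx) * r$wound,
             (1 - qx) * r$explant,
             (1 - qx) * r$failure,
             (1 - qx) * (1 - r$wound - r$explant - r$failure))
  )
  res
}

# Shared per-run precomputation for both engines.
.engine_setup <- function(params, arm, lt) {
  v <- validate_parameters(params)
  if (nrow(v) > 0) {
    stop("parameter validation failed (", nrow(v), " violation(s)); ",
         "see validate_parameters()", call. = FALSE)
  }
  strategy <- .resolve_strategy(params, arm)
  ec <- params$economic
  cl <- params$clinical
  ages <- ec$start_age:ec$horizon_end_age
  H <- length(ages)
  cyc <- seq_len(H)
  tsdv <- seq_len(H)
  cells <- .utility_cells(params$utilities)
  idx <- .band_index(params$utilities, ages)
  active_x <- .is_bilateral(strategy) & ages >= (strategy$age_second_implant %||% Inf)
  chain_start <- if (identical(strategy$arm, "SEQUENTIAL")) {
    strategy$age_second_implant
  } else {
    strategy$age_first_implant
  }
  U <- .schedule_units_matrix(params, strategy, H)
  costvec <- unlist(params$costs[.money_fields])
  list(
    strategy = strategy, ages = ages, H = H,
    vq = discount_factor(ec$discount_rate_annual, cyc, mid_cycle = TRUE),
    vc = discount_factor(ec$discount_rate_annual, cyc, mid_cycle = FALSE),
    qx = annual_death_probability(lt, ages),
    chain_start = chain_start,
    p_w = ifelse(tsdv == 1, cl$p_wound_first_year, cl$p_wound_subsequent),
    p_e = ifelse(tsdv == 1, cl$p_explant_first_year, cl$p_explant_subsequent),
    q_f = annual_failure_probability(params$reliability, tsdv),
    post_warranty = tsdv > cl$warranty_years,
    mult = strategy$replacement_cost_multiplier,
    U = U, costvec = costvec,
    sched_cost = as.numeric(crossprod(U, costvec)),
    u_age = {
      u <- cells$bimodal[idx]
      u + ifelse(active_x, cells$bilateral_extra[idx], 0)
    },
    cell_bim = cells$bimodal[idx],
    cell_x = cells$bilateral_extra[idx],
    scal = params$utilities$age_bands$scaling[idx],
    active_x = active_x,
    cost_wound = params$costs$surgery_wound_revision + params$costs$ward_day,
    cost_replace = params$costs$surgery_explant_reimplant + params$costs$ward_day,
    cost_device = params$costs$ci_device
  )
}

#' Run the deterministic cohort-expectation model for one arm
#'
#' Propagates the state-occupancy distribution cycle by cycle from the start
#' age through the horizon. Because the failure hazard and the first-year
#' complication rates depend on time since the current device's implantation,
#' occupancy is tracked jointly over (device state, device-clock year); the
#' reported per-cycle occupancy aggregates over the clock. Expected
#' discounted QALYs (half-cycle corrected) and costs are accrued exactly, so
#' cohort results are the exact expectation that the microsimulation
#' converges to.
#'
#' Alongside totals, the trace carries the expected discounted resource-unit
#' vector and utility-exposure coefficients. Arm-level cost is the dot
#' product of units with unit costs, and QALYs are linear in the two base
#' utility increments; the probabilistic sensitivity analysis relies on this
#' exact decomposition.
#'
#' @param params A `cea_parameters` object; must validate cleanly.
#' @param arm Strategy name (`"BIMODAL"`, `"SIMULTANEOUS"`, `"SEQUENTIAL"`)
#'   or a strategy definition.
#' @param lt A `life_table`.
#' @return A `cea_trace`: list with `cycles` (one row per cycle), `totals`
#'   (an `arm_result`), `resource_units`, `utility_exposure`, `arm`.
#' @export
run_cohort <- function(params, arm, lt) {
  s <- .engine_setup(params, arm, lt)
  H <- s$H
  occ <- matrix(0, 3, H)  # device state x years since current device
  pre <- 0                # alive, event chain not yet started (sequential)
  dead <- 0
  if (s$chain_start <= s$ages[1]) occ[1, 1] <- 1 else pre <- 1
  units <- stats::setNames(numeric(length(.money_fields)), .money_fields)
  expo <- c(printed_bimodal = 0, scaled_bimodal = 0,
            printed_extra = 0, scaled_extra = 0)
  cyc <- data.frame(
    cycle = seq_len(H), age = s$ages,
    occ_dev1 = NA_real_, occ_dev2 = NA_real_, occ_dev3 = NA_real_,
    occ_death = NA_real_, alive = NA_real_,
    qaly_disc = NA_real_, cost_scheduled_disc = NA_real_,
    cost_event_disc = NA_real_
  )
  for (i in seq_len(H)) {
    a <- s$ages[i]
    if (pre > 0 && a >= s$chain_start) {
      occ[1, 1] <- occ[1, 1] + pre
      pre <- 0
    }
    alive <- sum(occ) + pre
    # accrual: occupants at cycle start accrue the year's utility (credited
    # mid-cycle) and the year's scheduled costs (credited at cycle start)
    cyc$qaly_disc[i] <- alive * s$u_age[i] * s$vq[i]
    cyc$cost_scheduled_disc[i] <- alive * s$sched_cost[i] * s$vc[i]
    units <- units + s$U[, i] * alive * s$vc[i]
    expo["printed_bimodal"] <- expo["printed_bimodal"] + alive * s$cell_bim[i] * s$vq[i]
    expo["scaled_bimodal"] <- expo["scaled_bimodal"] + alive * s$scal[i] * s$vq[i]
    if (s$active_x[i]) {
      expo["printed_extra"] <- expo["printed_extra"] + alive * s$cell_x[i] * s$vq[i]
      expo["scaled_extra"] <- expo["scaled_extra"] + alive * s$scal[i] * s$vq[i]
    }
    cyc$occ_dev1[i] <- sum(occ[1, ]) + pre
    cyc$occ_dev2[i] <- sum(occ[2, ])
    cyc$occ_dev3[i] <- sum(occ[3, ])
    cyc$occ_death[i] <- dead
    cyc$alive[i] <- alive
    # transitions: death first, then complication, then failure
    surv <- occ * (1 - s$qx[i])
    dead <- dead + alive * s$qx[i]
    pre <- pre * (1 - s$qx[i])
    w_m <- sweep(surv, 2, s$p_w, `*`)
    e_m <- sweep(surv, 2, s$p_e, `*`)
    f_m <- sweep(surv, 2, (1 - s$p_w - s$p_e) * s$q_f, `*`)
    e_m[3, ] <- 0  # replacement cap
    f_m[3, ] <- 0
    wound_tot <- sum(w_m)
    repl <- e_m + f_m
    repl_tot <- sum(repl)
    repl_post <- sum(repl[, s$post_warranty, drop = FALSE])
    cyc$cost_event_disc[i] <- (wound_tot * s$cost_wound +
                               repl_tot * s$cost_replace +
                               repl_post * s$cost_device) * s$mult * s$vc[i]
    units["surgery_wound_revision"] <- units["surgery_wound_revision"] +
      wound_tot * s$mult * s$vc[i]
    units["ward_day"] <- units["ward_day"] + (wound_tot + repl_tot) * s$mult * s$vc[i]
    units["surgery_explant_reimplant"] <- units["surgery_explant_reimplant"] +
      repl_tot * s$mult * s$vc[i]
    units["ci_device"] <- units["ci_device"] + repl_post * s$mult * s$vc[i]
    stay <- surv - e_m - f_m  # wound revision stays in state, clock runs on
    nocc <- matrix(0, 3, H)
    nocc[, 2:H] <- stay[, 1:(H - 1)]
    nocc[, H] <- nocc[, H] + stay[, H]  # clock saturates at the horizon
    nocc[2, 1] <- sum(repl[1, ])
    nocc[3, 1] <- sum(repl[2, ])
    occ <- nocc
  }
  totals <- structure(
    list(arm = s$strategy$arm,
         discounted_cost = sum(cyc$cost_scheduled_disc) + sum(cyc$cost_event_disc),
         discounted_qaly = sum(cyc$qaly_disc),
         n = "cohort", standard_errors = NULL),
    class = "arm_result")
  structure(
    list(arm = s$strategy, cycles = cyc, totals = totals,
         resource_units = units, utility_exposure = expo,
         utility_basis = params$utilities[c("base_increment_bimodal",
                                            "base_increment_bilateral_extra",
                                            "printed_basis_bimodal",
                                            "printed_basis_bilateral")]),
    class = "cea_trace")
}

#' Run the Monte Carlo microsimulation for one arm
#'
#' Samples `n` independent individual trajectories through the same
#' transition structure as [run_cohort()] (one uniform draw resolves death,
#' a second resolves the competing wound/explant/failure events). Identical
#' `(params, arm, n, seed)` give bit-identical output.
#'
#' @param params A `cea_parameters` object; must validate cleanly.
#' @param arm Strategy name or definition.
#' @param lt A `life_table`.
#' @param n Number of simulated individuals.
#' @param seed Integer seed.
#' @return An `arm_result` with mean discounted cost and QALY, Monte Carlo
#'   standard errors, and the distribution of internal-device replacements
#'   (`replacement_table`, `max_replacements`).
#' @export
run_microsim <- function(params, arm, lt, n, seed) {
  stopifnot(n >= 1)
  s <- .engine_setup(params, arm, lt)
  set.seed(seed)
  H <- s$H
  dev <- rep(if (s$chain_start <= s$ages[1]) 1L else 0L, n)
  tsd <- rep(if (s$chain_start <= s$ages[1]) 1L else 0L, n)
  alive <- rep(TRUE, n)
  repl_count <- integer(n)
  qaly <- numeric(n)
  cost <- numeric(n)
  warranty <- params$clinical$warranty_years
  for (i in seq_len(H)) {
    a <- s$ages[i]
    if (a >= s$chain_start) {
      starting <- alive & dev == 0L
      dev[starting] <- 1L
      tsd[starting] <- 1L
    }
    qaly[alive] <- qaly[alive] + s$u_age[i] * s$vq[i]
    cost[alive] <- cost[alive] + s$sched_cost[i] * s$vc[i]
    u1 <- stats::runif(n)
    alive <- alive & u1 >= s$qx[i]
    act <- alive & dev > 0L
    ts <- pmax(tsd, 1L)
    p_w <- s$p_w[ts]
    p_e <- s$p_e[ts]
    p_f <- (1 - p_w - p_e) * s$q_f[ts]
    capped <- dev >= 3L
    p_e[capped] <- 0
    p_f[capped] <- 0
    u2 <- stats::runif(n)
    wound <- act & u2 < p_w
    expl <- act & !wound & u2 < p_w + p_e
    fail <- act & !wound & !expl & u2 < p_w + p_e + p_f
    repl <- expl | fail
    if (any(wound)) cost[wound] <- cost[wound] + s$cost_wound * s$mult * s$vc[i]
    if (any(repl)) {
      cost[repl] <- cost[repl] +
        (s$cost_replace + ifelse(tsd[repl] > warranty, s$cost_device, 0)) *
        s$mult * s$vc[i]
      dev[repl] <- dev[repl] + 1L
      repl_count[repl] <- repl_count[repl] + 1L
    }
    tsd[act] <- pmin(tsd[act] + 1L, H)
    tsd[repl] <- 1L
  }
  structure(
    list(arm = s$strategy$arm,
         discounted_cost = mean(cost),
         discounted_qaly = mean(qaly),
         n = n,
         standard_errors = c(cost = stats::sd(cost) / sqrt(n),
                             qaly = stats::sd(qaly) / sqrt(n)),
         max_replacements = max(repl_count),
         replacement_table = table(repl_count)),
    class = "arm_result")
}

#' @export
print.arm_result <- function(x, ...) {
  cat(sprintf("%s arm (%s): discounted cost %s USD, discounted QALY %.4f\n",
              x$arm, if (identical(x$n, "cohort")) "cohort expectation"
                     else paste0("microsimulation, n = ", x$n),
              format(round(x$discounted_cost), big.mark = ","),
              x$discounted_qaly))
  if (!is.null(x$standard_errors)) {
    cat(sprintf("  MC standard errors: cost %.1f, QALY %.5f\n",
                x$standard_errors["cost"], x$standard_errors["qaly"]))
  }
  invisible(x)
}

#' @export
print.cea_trace <- function(x, ...) {
  cat(sprintf("Cohort trace, %s arm: %d annual cycles (ages %d-%d)\n",
              x$arm$arm, nrow(x$cycles), min(x$cycles$age), max(x$cycles$age)))
  print(x$totals)
  invisible(x)
}
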