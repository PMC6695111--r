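# Internal-device reliability: cumulative survival of the implanted device as
# a function of years since implantation, and the annual failure probabilities
# the Markov engine consumes.
#
# Sign convention: the published extrapolation function is read as cumulative
# survival DECLINING linearly, S(t) = 0.998749 - 0.002911 * t. Read literally
# as a probability with a positive slope it would exceed 1, so the declining-
# survival reading is the only one consistent with survival data.

#' Construct a device-reliability curve
#'
#' @param year Integer years since implantation (>= 1), ascending.
#' @param cumulative_survival Proportion of devices still functioning at each
#'   year; non-increasing, in (0, 1].
#' @return An object of class `reliability_curve`.
#' @export
reliability_curve <- function(year, cumulative_survival) {
  stopifnot(length(year) == length(cumulative_survival), length(year) >= 1)
  ord <- order(year)
  year <- year[ord]; s <- cumulative_survival[ord]
  if (any(duplicated(year))) stop("duplicate years in reliability curve", call. = FALSE)
  if (any(year < 1)) stop("reliability years must be >= 1", call. = FALSE)
  if (any(s <= 0 | s > 1)) {
    stop("cumulative survival outside (0, 1] at row ", which(s <= 0 | s > 1)[1],
         call. = FALSE)
  }
  if (any(diff(s) > 0)) {
    stop("cumulative survival must be non-increasing (row ",
         which(diff(s) > 0)[1] + 1L, ")", call. = FALSE)
  }
  obj <- data.frame(year = as.integer(year), cumulative_survival = as.numeric(s))
  attr(obj, "observed_max_year") <- max(obj$year)
  class(obj) <- c("reliability_curve", "data.frame")
  obj
}

#' Read a reliability curve from CSV
#'
#' Expects a header `year,cumulative_survival`.
#'
#' @param path Path to a CSV file.
#' @return A `reliability_curve` object.
#' @export
read_reliability_curve <- function(path) {
  if (!file.exists(path)) stop("reliability file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path)
  if (nrow(df) == 0) stop("reliability file is empty: ", path, call. = FALSE)
  if (!all(c("year", "cumulative_survival") %in% names(df))) {
    stop("reliability file must have columns 'year' and 'cumulative_survival'",
         call. = FALSE)
  }
  reliability_curve(df$year, df$cumulative_survival)
}

#' Linear cumulative-survival model
#'
#' `S(t) = intercept - slope_per_year * t`, floored at a small positive
#' constant so hazards stay defined if queried past the valid range. The
#' defaults are the published extrapolation coefficients, valid from the 20th
#' to the 80th year of device use.
#'
#' @param intercept Survival proportion at year 0 of the fitted line.
#' @param slope_per_year Annual decline in cumulative survival.
#' @param valid_from_year First year the linear extrapolation applies.
#' @param valid_to_year Last year of the stated valid range.
#' @param floor Lower bound applied to extrapolated survival.
#' @param points Optional `reliability_curve` of observed annual points used
#'   inside the observed range (linear interpolation with `S(0) = 1`).
#' @return An object of class `reliability_model`.
#' @export
linear_survival_model <- function(intercept = 0.998749, slope_per_year = 0.002911,
                                  valid_from_year = 20, valid_to_year = 80,
                                  floor = 0.01, points = NULL) {
  stopifnot(is.numeric(intercept), is.numeric(slope_per_year), floor > 0)
  s_range <- intercept - slope_per_year * c(valid_from_year, valid_to_year)
  if (any(s_range <= 0 | s_range > 1)) {
    stop("linear survival model leaves (0, 1] over its valid range", call. = FALSE)
  }
  structure(list(intercept = intercept, slope_per_year = slope_per_year,
                 valid_from_year = valid_from_year, valid_to_year = valid_to_year,
                 floor = floor, points = points,
                 observed_max_year = if (is.null(points)) NULL else
                   attr(points, "observed_max_year")),
            class = "reliability_model")
}

#' Fit the linear extrapolation to an observed reliability curve
#'
#' Ordinary least squares through the `(year, cumulative_survival)` pairs; the
#' fitted decline is returned as a `reliability_model` whose extrapolation
#' applies from the year after the last observed one, with the observed points
#' retained for interpolation inside follow-up.
#'
#' @param curve A `reliability_curve` with at least two distinct years.
#' @return A `reliability_model`.
#' @export
fit_linear_extrapolation <- function(curve) {
  stopifnot(inherits(curve, "reliability_curve"))
  if (nrow(curve) < 2 || length(unique(curve$year)) < 2) {
    stop("fit error: need >= 2 distinct years to fit a line", call. = FALSE)
  }
  fit <- stats::lm(cumulative_survival ~ year, data = curve)
  co <- stats::coef(fit)
  linear_survival_model(
    intercept = unname(co[1]),
    slope_per_year = -unname(co[2]),  # stored as a decline
    valid_from_year = attr(curve, "observed_max_year") + 1L,
    points = curve
  )
}

#' Cumulative device survival at t years since implantation
#'
#' `S(0) = 1` (no device fails before use). Inside observed follow-up the
#' curve is linearly interpolated; beyond it the linear model applies, floored
#' at a small positive constant.
#'
#' @param model A `reliability_model` or `reliability_curve`.
#' @param t Years since implantation, `>= 0`; vectorised.
#' @return Survival proportion(s).
#' @export
cumulative_survival <- function(model, t) UseMethod("cumulative_survival")

#' @export
cumulative_survival.reliability_model <- function(model, t) {
  stopifnot(all(t >= 0))
  line_s <- pmax(model$intercept - model$slope_per_year * t, model$floor)
  if (is.null(model$points)) {
    # coefficients-only model: the line applies from year 1 on; interpolate
    # the sub-year gap between S(0) = 1 and S(1)
    s1 <- max(model$intercept - model$slope_per_year, model$floor)
    out <- ifelse(t >= 1, line_s, 1 + (s1 - 1) * t)
  } else {
    maxy <- model$observed_max_year
    interp <- stats::approx(x = c(0, model$points$year),
                            y = c(1, model$points$cumulative_survival),
                            xout = pmin(t, maxy))$y
    out <- ifelse(t <= maxy, interp, line_s)
  }
  out[t == 0] <- 1
  out
}

#' @export
cumulative_survival.reliability_curve <- function(model, t) {
  stopifnot(all(t >= 0))
  maxy <- attr(model, "observed_max_year")
  if (any(t > maxy)) {
    stop("query beyond observed follow-up (", maxy,
         " y); fit an extrapolation first", call. = FALSE)
  }
  stats::approx(x = c(0, model$year), y = c(1, model$cumulative_survival),
                xout = t)$y
}

#' Annual internal-device failure probability
#'
#' Conditional probability that a device functioning at the start of year `t`
#' of use fails during that year:
#' `q(t) = (S(t-1) - S(t)) / S(t-1)`, clamped to `[0, 1]`; returns 1 where
#' `S(t-1) = 0`.
#'
#' @param model A `reliability_model` or `reliability_curve`.
#' @param t Years since the current device's implantation, `>= 1`; vectorised.
#' @return Failure probability(ies).
#' @export
annual_failure_probability <- function(model, t) {
  stopifnot(all(t >= 1))
  s_prev <- cumulative_survival(model, t - 1)
  s_cur <- cumulative_survival(model, t)
  q <- ifelse(s_prev <= 0, 1, (s_prev - s_cur) / s_prev)
  pmin(pmax(q, 0), 1)
}

#' Reliability model packaged with the model
#'
#' Reads the packaged device-survival fixture (19 annual points lying on the
#' published linear extrapolation) and fits the extrapolation to it.
#'
#' @return A `reliability_model`.
#' @export
bicea_reliability <- function() {
  fit_linear_extrapolation(read_reliability_curve(
    system.file("extdata", "reliability_fixture.csv",
                package = "bicea", mustWork = TRUE)))
}
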