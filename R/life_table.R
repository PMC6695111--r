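# Age-dependent all-cause mortality: life-table I/O, lookup, and a
# Gompertz-Makeham generator standing in for an unpublished national table.

#' Construct a life table
#'
#' @param age Integer ages, consecutive and ascending.
#' @param qx Annual probability of death before the next birthday, one per age.
#' @return An object of class `life_table` (a data frame with columns
#'   `age` and `qx` plus a `max_age` attribute).
#' @export
life_table <- function(age, qx) {
  stopifnot(length(age) == length(qx), length(age) >= 1)
  ord <- order(age)
  age <- age[ord]; qx <- qx[ord]
  if (any(duplicated(age))) stop("duplicate ages in life table", call. = FALSE)
  if (any(diff(age) != 1)) stop("life-table ages must be consecutive integers", call. = FALSE)
  if (any(qx < 0 | qx > 1)) {
    stop("life-table qx outside [0, 1] at row ", which(qx < 0 | qx > 1)[1], call. = FALSE)
  }
  lt <- data.frame(age = as.integer(age), qx = as.numeric(qx))
  attr(lt, "max_age") <- max(lt$age)
  class(lt) <- c("life_table", "data.frame")
  lt
}

#' Read a life table from CSV
#'
#' Expects a header `age,qx`. Rows are sorted by age; the terminal `qx` is
#' coerced to 1 so the table closes out (this coercion is deliberate: the
#' model treats the last tabulated age as the end of life).
#'
#' @param path Path to a CSV file with columns `age` and `qx`.
#' @return A `life_table` object.
#' @export
read_life_table <- function(path) {
  if (!file.exists(path)) stop("life-table file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path)
  if (nrow(df) == 0) stop("life-table file is empty: ", path, call. = FALSE)
  if (!all(c("age", "qx") %in% names(df))) {
    stop("life-table file must have columns 'age' and 'qx'", call. = FALSE)
  }
  if (!is.numeric(df$age) || !is.numeric(df$qx) || anyNA(df$age) || anyNA(df$qx)) {
    stop("life-table cells must be numeric", call. = FALSE)
  }
  df <- df[order(df$age), ]
  df$qx[nrow(df)] <- 1
  life_table(df$age, df$qx)
}

#' Synthetic national life table packaged with the model
#'
#' A Gompertz-Makeham table calibrated to a life expectancy at birth of 83
#' years, standing in for the (unpublished) high-longevity national table the
#' base case relies on. See the packaged `manifest.json`.
#'
#' @return A `life_table` object.
#' @export
bicea_life_table <- function() {
  read_life_table(system.file("extdata", "synthetic_sg_lifetable.csv",
                              package = "bicea", mustWork = TRUE))
}

#' Annual probability of death at a given age
#'
#' Ages beyond the table's maximum return 1 (the table closes out); ages below
#' the first tabulated age are an error, since the model never queries them.
#'
#' @param lt A `life_table`.
#' @param age Age(s) in whole years.
#' @return Numeric vector of annual death probabilities.
#' @export
annual_death_probability <- function(lt, age) {
  stopifnot(inherits(lt, "life_table"))
  if (any(age < lt$age[1])) {
    stop("age below first tabulated age (", lt$age[1], ")", call. = FALSE)
  }
  idx <- match(pmin(age, attr(lt, "max_age")), lt$age)
  out <- lt$qx[idx]
  out[age > attr(lt, "max_age")] <- 1
  out
}

#' Life expectancy at birth from a life table
#'
#' Standard lx method: the sum over ages of cumulative survival from the first
#' tabulated age, i.e. the expected number of whole years lived.
#'
#' @param lt A `life_table`.
#' @return Life expectancy (years) at the first tabulated age.
#' @export
life_expectancy <- function(lt) {
  stopifnot(inherits(lt, "life_table"))
  sum(cumprod(1 - lt$qx))
}

#' Build a Gompertz-Makeham life table
#'
#' Annual death probabilities follow
#' `qx(age) = 1 - exp(-(A + B * c^age))` for ages `0 .. max_age - 1`, with
#' `qx(max_age) = 1`: a constant background hazard `A` (Makeham term) plus a
#' senescent hazard growing geometrically in age (Gompertz term).
#'
#' @param makeham_a Age-independent hazard component (per year), `>= 0`.
#' @param gompertz_b Baseline senescent hazard (per year), `> 0`.
#' @param gompertz_c Rate ratio per year of age, `> 1`.
#' @param max_age Terminal age of the table.
#' @return A `life_table` object.
#' @export
make_gompertz_makeham_table <- function(makeham_a, gompertz_b, gompertz_c, max_age) {
  if (!(makeham_a >= 0)) stop("makeham_a must be >= 0", call. = FALSE)
  if (!(gompertz_b > 0)) stop("gompertz_b must be > 0", call. = FALSE)
  if (!(gompertz_c > 1)) stop("gompertz_c must be > 1", call. = FALSE)
  ages <- 0:max_age
  qx <- 1 - exp(-(makeham_a + gompertz_b * gompertz_c^ages))
  qx[length(qx)] <- 1
  life_table(ages, qx)
}

#' Calibrate the Gompertz slope to a target life expectancy
#'
#' Bisection on `gompertz_b` until the generated table's life expectancy at
#' birth (lx method, recomputed from the emitted table) is within 0.05 years
#' of `target_e0`.
#'
#' @param target_e0 Target life expectancy at birth (years).
#' @param makeham_a Fixed Makeham hazard; default 0.0002/yr.
#' @param gompertz_c Fixed rate ratio per year of age; default 1.10.
#' @param max_age Terminal age; default 100.
#' @return A list with fields `makeham_a`, `gompertz_b`, `gompertz_c`,
#'   `max_age` (class `gompertz_makeham_params`).
#' @export
calibrate_to_life_expectancy <- function(target_e0, makeham_a = 0.0002,
                                         gompertz_c = 1.10, max_age = 100) {
  e0_of <- function(b) {
    life_expectancy(make_gompertz_makeham_table(makeham_a, b, gompertz_c, max_age))
  }
  lo <- 1e-12; hi <- 1
  if (!(e0_of(lo) >= target_e0 && e0_of(hi) <= target_e0)) {
    stop("calibration error: target life expectancy ", target_e0,
         " not bracketed for the given hazard parameters", call. = FALSE)
  }
  for (i in 1:200) {
    mid <- sqrt(lo * hi)  # bisect on log scale; b spans orders of magnitude
    e <- e0_of(mid)
    if (abs(e - target_e0) <= 0.05) break
    if (e > target_e0) lo <- mid else hi <- mid
  }
  if (abs(e0_of(mid) - target_e0) > 0.05) {
    stop("calibration error: bisection did not converge", call. = FALSE)
  }
  structure(list(makeham_a = makeham_a, gompertz_b = mid,
                 gompertz_c = gompertz_c, max_age = max_age),
            class = "gompertz_makeham_params")
}
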