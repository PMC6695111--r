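# Single source of truth for every model parameter: economic settings,
# clinical event probabilities, the age-banded utility schedule, unit costs,
# the resource-use schedule and the device-reliability model.

# Money-valued unit-cost fields. The order is part of the package contract:
# it fixes the PSA sampling stream and the layout of resource-unit vectors.
.money_fields <- c(
  "surgery_implantation", "surgery_wound_revision", "surgery_explant_reimplant",
  "ward_day", "ci_device", "hearing_aid", "aided_hearing_test",
  "audiologist_session", "auditory_assessment", "avt_slp_session",
  "ct_scan", "ent_review", "speech_assessment", "external_processor_replacement"
)

.default_age_bands <- function() {
  data.frame(
    age_low  = c(1, 2, 4, 55, 65, 70, 75, 80),
    age_high = c(1, 3, 54, 64, 69, 74, 79, 84),
    scaling  = c(0.28, 0.91, 1.00, 0.98, 0.96, 0.91, 0.84, 0.72),
    printed_bimodal   = c(0.066, 0.212, 0.232, 0.227, 0.223, 0.211, 0.195, 0.167),
    printed_bilateral = c(0.009, 0.027, 0.030, 0.0294, 0.0288, 0.0273, 0.0252, 0.0216)
  )
}

.default_strategies <- function() {
  list(
    BIMODAL = list(arm = "BIMODAL", age_first_implant = 1,
                   age_second_implant = NA_real_, replacement_cost_multiplier = 1),
    SIMULTANEOUS = list(arm = "SIMULTANEOUS", age_first_implant = 1,
                        age_second_implant = 1, replacement_cost_multiplier = 2),
    SEQUENTIAL = list(arm = "SEQUENTIAL", age_first_implant = 1,
                      age_second_implant = 3, replacement_cost_multiplier = 2)
  )
}

#' Build a fully specified parameter set
#'
#' Assembles the complete model parameterisation: 3% annual discounting over
#' annual cycles from age 1 through age 84, first-year/subsequent clinical
#' event probabilities, the age-banded utility schedule (bimodal gain 0.232/yr
#' and bilateral-over-bimodal gain 0.03/yr at full realisation), 2017 USD unit
#' costs, the incremental resource-use schedule, and the linear internal-device
#' survival model.
#'
#' The replacement cost of the external sound processor is not a published
#' quantity and therefore has no default: it must be supplied explicitly. The
#' packaged fixture ([bicea_parameters()]) carries a reconstructed value
#' calibrated so the simultaneous-vs-bimodal incremental cost matches the
#' published base case (see [calibrate_processor_cost()]).
#'
#' @param external_processor_replacement Unit cost (USD) of a replacement
#'   external sound processor. Required.
#' @return An object of class `cea_parameters`.
#' @seealso [load_parameters()], [validate_parameters()], [apply_override()]
#' @export
default_parameters <- function(external_processor_replacement) {
  if (missing(external_processor_replacement) ||
      !is.numeric(external_processor_replacement) ||
      length(external_processor_replacement) != 1L ||
      is.na(external_processor_replacement)) {
    stop("missing required field 'costs.external_processor_replacement' ",
         "(no published value exists; supply one explicitly)", call. = FALSE)
  }
  costs <- list(
    surgery_implantation = 4940,
    surgery_wound_revision = 6454,
    surgery_explant_reimplant = 7115,
    ward_day = 172,
    ci_device = 28216,
    hearing_aid = 949,
    aided_hearing_test = 29,
    audiologist_session = 81,
    auditory_assessment = 53,
    avt_slp_session = 116,
    ct_scan = 405,
    ent_review = 57,
    speech_assessment = 35,
    external_processor_replacement = external_processor_replacement,
    external_processor_cycle_years = 7,
    hearing_aid_cycle_years = 5,
    initial_implant_cost_multiplier = 1
  )
  strategies <- .default_strategies()
  params <- list(
    economic = list(
      discount_rate_annual = 0.03,
      cycle_length = 1,
      start_age = 1,
      horizon_end_age = 84,
      currency_label = "USD",
      sgd_per_usd = 1.317,
      half_cycle_on_qalys_only = TRUE
    ),
    clinical = list(
      p_major_first_year = 0.01,
      p_major_subsequent = 0.001,
      p_wound_first_year = 0.005,
      p_wound_subsequent = 0.0005,
      p_explant_first_year = 0.005,
      p_explant_subsequent = 0.0005,
      max_internal_replacements = 2,
      warranty_years = 10,
      first_implant_complications_in_sequential = FALSE
    ),
    utilities = list(
      base_increment_bimodal = 0.232,
      base_increment_bilateral_extra = 0.03,
      printed_basis_bimodal = 0.232,
      printed_basis_bilateral = 0.03,
      age_bands = .default_age_bands()
    ),
    costs = costs,
    strategies = strategies,
    resource_schedule = default_resource_schedule(
      strategies,
      processor_cycle_years = costs$external_processor_cycle_years,
      hearing_aid_cycle_years = costs$hearing_aid_cycle_years
    ),
    reliability = linear_survival_model(),
    psa = list(cv_costs = 1.0, cv_utilities = 1.0),
    life_table_ref = "synthetic_sg_lifetable.csv"
  )
  class(params) <- "cea_parameters"
  params
}

#' Load model parameters from YAML
#'
#' Reads a parameter file (or literal YAML text) against the documented schema
#' (see `inst/extdata/parameters.schema`). Missing optional fields take the
#' published defaults; `costs.external_processor_replacement` is required and
#' its absence is an error, never a silent default.
#'
#' @param config Path to a YAML file, or a character string of YAML text.
#' @return A `cea_parameters` object.
#' @export
load_parameters <- function(config) {
  stopifnot(is.character(config), length(config) == 1L)
  y <- if (file.exists(config)) yaml::read_yaml(config) else yaml::yaml.load(config)
  if (!is.list(y)) stop("parameter config did not parse to a mapping", call. = FALSE)

  known_groups <- c("economic", "clinical", "utilities", "costs", "strategies",
                    "resource_schedule", "reliability", "psa", "life_table_ref",
                    "manifest")
  unknown <- setdiff(names(y), known_groups)
  if (length(unknown) > 0) {
    stop("unknown key(s) in parameter config: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  proc <- y$costs$external_processor_replacement
  if (is.null(proc)) {
    stop("missing required field 'costs.external_processor_replacement'",
         call. = FALSE)
  }
  params <- default_parameters(as.numeric(proc))

  merge_group <- function(group) {
    src <- y[[group]]
    if (is.null(src)) return()
    unknown <- setdiff(names(src), names(params[[group]]))
    if (length(unknown) > 0) {
      stop(sprintf("unknown key(s) in '%s': %s", group,
                   paste(unknown, collapse = ", ")), call. = FALSE)
    }
    for (k in names(src)) {
      if (k == "age_bands") next
      val <- src[[k]]
      # YAML parses whole numbers as integer; the schema is double-valued
      if (is.numeric(params[[group]][[k]]) && is.numeric(val)) val <- as.numeric(val)
      params[[group]][[k]] <<- val
    }
  }
  merge_group("economic")
  merge_group("clinical")
  merge_group("utilities")
  merge_group("costs")

  if (!is.null(y$utilities$age_bands)) {
    ab <- do.call(rbind, lapply(y$utilities$age_bands, function(b) {
      as.data.frame(b[c("age_low", "age_high", "scaling",
                        "printed_bimodal", "printed_bilateral")])
    }))
    params$utilities$age_bands <- ab
  }
  if (!is.null(y$strategies)) {
    for (nm in names(y$strategies)) {
      if (!nm %in% names(params$strategies)) {
        stop("unknown strategy: ", nm, call. = FALSE)
      }
      s <- y$strategies[[nm]]
      s$arm <- nm
      if (is.null(s$age_second_implant)) s$age_second_implant <- NA_real_
      params$strategies[[nm]] <- s[c("arm", "age_first_implant",
                                     "age_second_implant",
                                     "replacement_cost_multiplier")]
    }
  }
  if (!is.null(y$resource_schedule)) {
    params$resource_schedule <- list(
      scheduled = do.call(rbind, lapply(y$resource_schedule$scheduled, as.data.frame)),
      periodic = do.call(rbind, lapply(y$resource_schedule$periodic, as.data.frame))
    )
  } else {
    # periodic cycles follow any overridden cycle-year costs
    params$resource_schedule <- default_resource_schedule(
      params$strategies,
      processor_cycle_years = params$costs$external_processor_cycle_years,
      hearing_aid_cycle_years = params$costs$hearing_aid_cycle_years
    )
  }
  if (!is.null(y$reliability)) {
    r <- y$reliability
    params$reliability <- linear_survival_model(
      intercept = r$intercept %||% 0.998749,
      slope_per_year = r$slope_per_year %||% 0.002911,
      valid_from_year = r$valid_from_year %||% 20,
      valid_to_year = r$valid_to_year %||% 80,
      floor = r$floor %||% 0.01
    )
  }
  if (!is.null(y$psa)) params$psa <- utils::modifyList(params$psa, y$psa)
  if (!is.null(y$life_table_ref)) params$life_table_ref <- y$life_table_ref
  params
}

#' Parameters mirroring the published tables
#'
#' Loads the packaged parameter fixture, which reproduces the published
#' transition probabilities, utility schedule, resource-use schedule and unit
#' costs cell-for-cell, plus the reconstructed (calibrated) external-processor
#' replacement cost. See the packaged `manifest.json` for which values are
#' reconstructed rather than published.
#'
#' @return A `cea_parameters` object.
#' @export
bicea_parameters <- function() {
  load_parameters(system.file("extdata", "published_tables.yaml",
                              package = "bicea", mustWork = TRUE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialise parameters to YAML
#'
#' Inverse of [load_parameters()]: `load_parameters(serialise_parameters(p))`
#' reproduces `p` field-for-field.
#'
#' @param params A `cea_parameters` object.
#' @return A single YAML character string.
#' @export
serialise_parameters <- function(params) {
  stopifnot(inherits(params, "cea_parameters"))
  ab <- params$utilities$age_bands
  out <- list(
    economic = params$economic,
    clinical = params$clinical,
    utilities = c(
      params$utilities[c("base_increment_bimodal", "base_increment_bilateral_extra",
                         "printed_basis_bimodal", "printed_basis_bilateral")],
      list(age_bands = lapply(seq_len(nrow(ab)), function(i) as.list(ab[i, ])))
    ),
    costs = params$costs,
    strategies = lapply(params$strategies, function(s) {
      s[!vapply(s, function(x) length(x) == 1 && is.na(x), logical(1))]
    }),
    resource_schedule = list(
      scheduled = lapply(seq_len(nrow(params$resource_schedule$scheduled)),
                         function(i) as.list(params$resource_schedule$scheduled[i, ])),
      periodic = lapply(seq_len(nrow(params$resource_schedule$periodic)),
                        function(i) as.list(params$resource_schedule$periodic[i, ]))
    ),
    reliability = unclass(params$reliability)[c("intercept", "slope_per_year",
                                                "valid_from_year", "valid_to_year",
                                                "floor")],
    psa = params$psa,
    life_table_ref = params$life_table_ref
  )
  yaml::as.yaml(out)
}

# number of decimal places a printed table cell is stated to
.printed_decimals <- function(x) {
  s <- format(x, scientific = FALSE, trim = TRUE)
  if (!grepl("\\.", s)) return(0L)
  nchar(sub("0+$", "", sub("^[^.]*\\.", "", s)))
}

#' Validate a parameter set
#'
#' Checks every structural invariant of the parameterisation and returns the
#' violations as data, not exceptions: probability bounds, the additivity of
#' wound-revision and explantation probabilities to the major-complication
#' probability, band contiguity of the utility schedule, consistency of the
#' printed bilateral utility cells with `scaling x base` (the age-1 cell is a
#' documented exception in the source tables and is not checked),
#' non-negativity of costs, and the reliability line staying inside (0, 1].
#'
#' @param params A `cea_parameters` object.
#' @return A data frame with columns `field`, `rule`, `value`; zero rows when
#'   the parameter set is valid. Never mutates `params`.
#' @export
validate_parameters <- function(params) {
  v <- list()
  bad <- function(field, rule, value) {
    v[[length(v) + 1L]] <<- data.frame(field = field, rule = rule,
                                       value = as.character(value)[1])
  }
  ec <- params$economic
  if (!(ec$discount_rate_annual >= 0 && ec$discount_rate_annual < 1)) {
    bad("economic.discount_rate_annual", "0 <= rate < 1", ec$discount_rate_annual)
  }
  if (!(ec$start_age < ec$horizon_end_age)) {
    bad("economic.start_age", "start_age < horizon_end_age", ec$start_age)
  }
  cl <- params$clinical
  for (f in c("p_major_first_year", "p_major_subsequent", "p_wound_first_year",
              "p_wound_subsequent", "p_explant_first_year", "p_explant_subsequent")) {
    if (!(cl[[f]] >= 0 && cl[[f]] <= 1)) {
      bad(paste0("clinical.", f), "probability in [0, 1]", cl[[f]])
    }
  }
  if (abs(cl$p_wound_first_year + cl$p_explant_first_year - cl$p_major_first_year) > 1e-12) {
    bad("clinical.p_major_first_year", "p_wound + p_explant = p_major (first year)",
        cl$p_major_first_year)
  }
  if (abs(cl$p_wound_subsequent + cl$p_explant_subsequent - cl$p_major_subsequent) > 1e-12) {
    bad("clinical.p_major_subsequent", "p_wound + p_explant = p_major (subsequent)",
        cl$p_major_subsequent)
  }
  us <- params$utilities
  ab <- us$age_bands
  if (nrow(ab) > 1 && any(ab$age_low[-1] != ab$age_high[-nrow(ab)] + 1)) {
    bad("utilities.age_bands", "bands contiguous, non-overlapping, ascending", "bands")
  }
  if (any(!(ab$scaling > 0 & ab$scaling <= 1))) {
    bad("utilities.age_bands.scaling", "scaling factors in (0, 1]",
        ab$scaling[which(!(ab$scaling > 0 & ab$scaling <= 1))[1]])
  }
  # printed bilateral cells agree with scaling x base at each cell's own
  # printed precision, for every band but the first
  for (i in seq_len(nrow(ab))[-1]) {
    d <- .printed_decimals(ab$printed_bilateral[i])
    if (round(ab$scaling[i] * us$printed_basis_bilateral, d) != ab$printed_bilateral[i]) {
      bad(sprintf("utilities.age_bands.printed_bilateral[%d]", i),
          "printed cell = round(scaling x base, printed precision)",
          ab$printed_bilateral[i])
    }
  }
  for (f in .money_fields) {
    if (!(params$costs[[f]] >= 0)) bad(paste0("costs.", f), "cost >= 0", params$costs[[f]])
  }
  for (f in c("external_processor_cycle_years", "hearing_aid_cycle_years")) {
    if (!(params$costs[[f]] > 0)) bad(paste0("costs.", f), "cycle > 0", params$costs[[f]])
  }
  for (s in params$strategies) {
    if (!is.na(s$age_second_implant) && s$age_second_implant < s$age_first_implant) {
      bad(paste0("strategies.", s$arm, ".age_second_implant"),
          "age_second_implant >= age_first_implant", s$age_second_implant)
    }
  }
  rel <- params$reliability
  s_range <- rel$intercept - rel$slope_per_year * c(1, rel$valid_to_year)
  if (any(s_range <= 0) || any(s_range > 1)) {
    bad("reliability", "S(t) in (0, 1] over the valid range", min(s_range))
  }
  if (length(v) == 0) {
    data.frame(field = character(), rule = character(), value = character())
  } else {
    do.call(rbind, v)
  }
}

#' List the dotted paths that [apply_override()] accepts
#'
#' @param params A `cea_parameters` object.
#' @return Character vector of valid dotted field names.
#' @export
param_paths <- function(params) {
  groups <- c("economic", "clinical", "costs", "reliability")
  paths <- unlist(lapply(groups, function(g) {
    fields <- names(params[[g]])
    keep <- vapply(params[[g]], function(x) is.numeric(x) && length(x) == 1L,
                   logical(1))
    paste0(g, ".", fields[keep])
  }))
  c(paths, "utilities.base_increment_bimodal", "utilities.base_increment_bilateral_extra")
}

#' Override a single numeric parameter
#'
#' Returns a new parameter set differing from `params` only at the dotted
#' `path`; the original is untouched. This is the mechanism the one-way
#' sensitivity analysis uses to perturb one parameter at a time.
#'
#' @param params A `cea_parameters` object.
#' @param path Dotted field name, e.g. `"costs.ci_device"`.
#' @param value Replacement numeric value.
#' @return A new `cea_parameters` object.
#' @export
apply_override <- function(params, path, value) {
  stopifnot(inherits(params, "cea_parameters"), is.numeric(value), length(value) == 1L)
  valid <- param_paths(params)
  if (!path %in% valid) {
    stop("unknown parameter path '", path, "'; valid paths:\n  ",
         paste(valid, collapse = "\n  "), call. = FALSE)
  }
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  params[[parts[1]]][[parts[2]]] <- value
  # periodic schedule rows carry their cycle length; keep them in step
  if (path %in% c("costs.external_processor_cycle_years", "costs.hearing_aid_cycle_years")) {
    params$resource_schedule <- default_resource_schedule(
      params$strategies,
      processor_cycle_years = params$costs$external_processor_cycle_years,
      hearing_aid_cycle_years = params$costs$hearing_aid_cycle_years
    )
  }
  params
}

#' @export
print.cea_parameters <- function(x, ...) {
  cat("Model parameters (class cea_parameters)\n")
  cat(sprintf("  discounting: %.1f%%/yr, ages %d-%d, annual cycles\n",
              100 * x$economic$discount_rate_annual,
              x$economic$start_age, x$economic$horizon_end_age))
  cat(sprintf("  utility increments: bimodal %.3f, bilateral extra %.3f (full realisation)\n",
              x$utilities$base_increment_bimodal,
              x$utilities$base_increment_bilateral_extra))
  cat(sprintf("  device: %s %s, processor %s %s (replaced every %d y)\n",
              format(x$costs$ci_device, big.mark = ","), x$economic$currency_label,
              format(x$costs$external_processor_replacement, big.mark = ","),
              x$economic$currency_label, x$costs$external_processor_cycle_years))
  nv <- nrow(validate_parameters(x))
  cat(sprintf("  validation: %s\n", if (nv == 0) "clean" else paste(nv, "violation(s)")))
  invisible(x)
}

.resolve_strategy <- function(params, arm) {
  if (is.character(arm)) {
    if (!arm %in% names(params$strategies)) {
      stop("unknown strategy '", arm, "'; expected one of: ",
           paste(names(params$strategies), collapse = ", "), call. = FALSE)
    }
    params$strategies[[arm]]
  } else {
    stopifnot(is.list(arm), !is.null(arm$arm))
    arm
  }
}

.is_bilateral <- function(strategy) !is.na(strategy$age_second_implant)
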