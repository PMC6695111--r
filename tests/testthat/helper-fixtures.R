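# Shared fixtures: the packaged parameter set, synthetic life table and
# fitted reliability model, loaded once per test run.

fx_params <- bicea_parameters()
fx_lt <- bicea_life_table()
fx_rel <- bicea_reliability()

# a strategy handle for quick utility/transition queries
fx_arm <- function(name) fx_params$strategies[[name]]

# zero-mortality life table (deaths only at the terminal age), for
# deterministic engine checks
flat_life_table <- function(max_age = 100) {
  life_table(0:max_age, c(rep(0, max_age), 1))
}

# reliability model with no failures at all
no_failure_reliability <- function() {
  linear_survival_model(intercept = 1, slope_per_year = 0)
}

# parameters stripped of all stochastic events (no complications, no
# failures); mortality comes from whatever life table is passed alongside
eventless_params <- function(params = fx_params) {
  for (p in c("p_major_first_year", "p_major_subsequent", "p_wound_first_year",
              "p_wound_subsequent", "p_explant_first_year", "p_explant_subsequent")) {
    params <- apply_override(params, paste0("clinical.", p), 0)
  }
  params$reliability <- no_failure_reliability()
  params
}
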