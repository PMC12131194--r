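# shared fixtures; heavyweight objects are computed once per session
.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

settled_sr_state <- function() {
  fixture("sr_state", function() settle_cell(crn_params("SR"), 20000))
}

settled_af_state <- function() {
  fixture("af_state", function() settle_cell(crn_params("AF"), 20000))
}

# analytic triangle AP: rest -80 mV, jump to +20 mV at t = 10 ms,
# linear return to -80 mV over 200 ms
triangle_trace <- function(dt = 1) {
  tt <- seq(0, 250, by = dt)
  vm <- ifelse(tt < 10, -80, pmax(20 - 100 * (tt - 10) / 200, -80))
  list(time = tt, vm = vm)
}

# 10-model cable-arm population, subsampled from a calibrated 40-sample
# LHS pool (the trial design at reduced scale)
af_trial_population <- function() {
  fixture("af_pop", function() {
    gen_population_fixture(n_target = 10, phenotype = "AF", seed = 11,
                           n_lhs = 40)
  })
}

calibrated_cable <- function() {
  fixture("cable_cfg", function() {
    cal <- calibrate_diffusion(crn_params("AF"), target_cv = 80, tol = 1)
    cable_config(diff_coef = cal$diff_coef)
  })
}
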