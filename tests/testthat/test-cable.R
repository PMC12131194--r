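test_that("zero-flux diffusion conserves total voltage when reaction is off", {
  cfg <- cable_config(n_cells = 40, diff_coef = 2e-3,
                      cv_cells = c(10, 30), distal_cell = 38)
  st <- matrix(crn_initial_state(), 21, 40)
  st[1, ] <- -80 + 40 * exp(-((1:40) - 10)^2 / 20)  # a bump to diffuse
  out <- solve_cable(cfg, crn_params(), numeric(0), duration = 50,
                     state0 = st, reaction = FALSE)
  expect_equal(sum(out$state[1, ]), sum(st[1, ]), tolerance = 1e-8)
  # and no activations are produced by pure diffusion
  expect_true(all(lengths(out$activations) == 0))
})

test_that("a sub-threshold stimulus never activates beyond the paced cells", {
  cfg <- cable_config(diff_coef = 2e-3)
  out <- solve_cable(cfg, crn_params(), 10, duration = 300,
                     state0 = settled_sr_state(), stim_amplitude = 5)
  expect_true(all(lengths(out$activations[4:100]) == 0))
})

test_that("CV arithmetic is exact and equal activation times error", {
  cfg <- cable_config()
  act <- rep(list(numeric(0)), 100)
  act[[26]] <- 10; act[[76]] <- 22.5    # 1 cm in 12.5 ms -> 80 cm/s
  expect_equal(measure_cv(act, cfg), 80)
  act[[76]] <- 10
  expect_error(measure_cv(act, cfg), "unphysical")
  act[[76]] <- numeric(0)
  blocked <- measure_cv(act, cfg)
  expect_true(is.na(blocked))
  expect_true(attr(blocked, "conduction_block"))
})

test_that("CV scales like the square root of the diffusion coefficient", {
  p <- crn_params("SR")
  st <- settled_sr_state()
  cv1 <- afsilico:::.cv_once(cable_config(), p, 1e-3, st, 0.02)
  cv4 <- afsilico:::.cv_once(cable_config(), p, 4e-3, st, 0.02)
  expect_lt(abs(cv4 / cv1 - 2), 0.2)   # quadrupling D ~ doubles CV
})

test_that("planar CV is uniform along the strand and robust to cable length", {
  p <- crn_params("SR")
  st <- settled_sr_state()
  cfg <- cable_config(diff_coef = 2.5e-3)
  out <- solve_cable(cfg, p, 10, 120, state0 = st)
  cv_wide <- measure_cv(out$activations, cfg, c(26, 76))
  cv_narrow <- measure_cv(out$activations, cfg, c(41, 61))
  expect_lt(abs(cv_wide - cv_narrow) / cv_wide, 0.02)
  # doubling the cable changes CV by < 2%
  cfg2 <- cable_config(n_cells = 200, diff_coef = 2.5e-3,
                       cv_cells = c(26, 76), distal_cell = 196)
  out2 <- solve_cable(cfg2, p, 10, 200, state0 = st)
  cv2 <- measure_cv(out2$activations, cfg2, c(26, 76))
  expect_lt(abs(cv2 - cv_wide) / cv_wide, 0.02)
})

test_that("an unstable diffusion configuration is refused before stepping", {
  cfg <- cable_config(diff_coef = 0.2)
  expect_error(solve_cable(cfg, crn_params(), 10, 50), "unstable")
})

test_that("diffusion calibration hits the 80 cm/s bulk-velocity target", {
  cfg <- calibrated_cable()
  expect_gte(cfg$diff_coef, 0)
  cal <- calibrate_diffusion(crn_params("AF"), target_cv = 80, tol = 1,
                             bracket = c(cfg$diff_coef / 2,
                                         cfg$diff_coef * 2))
  expect_gt(cal$cv, 79); expect_lt(cal$cv, 81)
  # a target already met by the initial bracket midpoint returns quickly
  again <- calibrate_diffusion(crn_params("AF"), target_cv = cal$cv,
                               tol = 2, bracket = c(cal$diff_coef * 0.9,
                                                    cal$diff_coef * 1.1))
  expect_lte(again$iterations, 3)
})

test_that("binary-search ERP equals the exhaustive linear scan", {
  cfg <- calibrated_cable()
  prot <- s1s2_protocol(n_s1 = 6, s2_bounds = c(100, 280), resolution = 10)
  pop <- af_trial_population()
  for (i in 1:3) {
    p <- apply_scaling(crn_params("AF"), pop$scalings[i, ])
    eb <- measure_erp(p, cfg, prot, search = "binary")
    el <- measure_erp(p, cfg, prot, search = "linear")
    expect_true(eb$s1_captured)
    expect_equal(eb$erp_ms, el$erp_ms)
  }
})

test_that("drug block prolongs refractoriness and slows conduction", {
  cfg <- calibrated_cable()
  p <- crn_params("AF")
  prot <- s1s2_protocol(n_s1 = 6)
  e0 <- measure_erp(p, cfg, prot)
  e100 <- measure_erp(apply_block(p, block_profile_6f(100)), cfg, prot)
  expect_gt(e100$erp_ms, e0$erp_ms)
  # 65% I_Na block slows the planar wave
  st <- settled_af_state()
  cv0 <- afsilico:::.cv_once(cfg, p, cfg$diff_coef, st, 0.02)
  p_na <- p; p_na["g_na"] <- p["g_na"] * (1 - 0.65)
  st_na <- settle_cell(p_na, 20000)
  cv_na <- afsilico:::.cv_once(cfg, p_na, cfg$diff_coef, st_na, 0.02)
  expect_lt(cv_na, cv0)
})

test_that("propagation follows rate versus refractoriness", {
  cfg <- calibrated_cable()
  p <- crn_params("AF")
  ok1 <- propagation_check(p, cfg, rate = 1, n_stimuli = 5, n_pre = 2)
  expect_true(ok1$success)
  expect_lte(ok1$captures, 5)
  # pacing faster than the measured ERP allows must fail 1:1
  e <- measure_erp(apply_block(p, block_profile_6f(100)), cfg,
                   s1s2_protocol(n_s1 = 6))
  fast <- 1000 / (e$erp_ms * 0.8)
  bad <- propagation_check(apply_block(p, block_profile_6f(100)), cfg,
                           rate = fast, n_stimuli = 5, n_pre = 5)
  expect_false(bad$success)
})
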