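test_that("I_K2P obeys Nernst reversal, linearity, and outward rectification", {
  rtf <- 8.3143 * 310 / 96.4867
  ek <- rtf * log(5.4 / 139)
  expect_equal(ik2p_current(ek, 5.4, 139, 0.01), 0, tolerance = 1e-10)
  expect_equal(ik2p_current(-20, 5.4, 139, 0), 0)
  # linear in conductance
  i1 <- ik2p_current(-20, 5.4, 139, 0.002)
  i2 <- ik2p_current(-20, 5.4, 139, 0.004)
  expect_equal(i2, 2 * i1, tolerance = 1e-12)
  # sign flips exactly at E_K
  expect_gt(ik2p_current(ek + 5, 5.4, 139, 0.002), 0)
  expect_lt(ik2p_current(ek - 5, 5.4, 139, 0.002), 0)
  # outward (GHK) rectification: outward chord conductance exceeds inward
  g_out <- ik2p_current(ek + 60, 5.4, 139, 0.002) / 60
  g_in <- -ik2p_current(ek - 60, 5.4, 139, 0.002) / 60
  expect_gt(g_out, g_in)
  expect_error(ik2p_current(-20, -1, 139, 0.002), "positive")
})

test_that("resting state is a fixed point and is stable over 10 s", {
  p <- crn_params("SR")
  st <- settled_sr_state()
  d <- cell_derivatives(st, p, i_stim = 0)
  expect_lt(abs(d$dy[["vm"]]), 1e-3)
  tr <- integrate_cell(st, p, NULL, duration = 10000, dt = 0.02,
                       sample_dt = 10)
  expect_lt(max(abs(tr$vm - tr$vm[1])), 1)
})

test_that("voltage-clamped gate derivatives drive gates toward steady state", {
  p <- crn_params("SR")
  st <- settled_sr_state()
  st["vm"] <- 0   # clamp far from rest
  d <- cell_derivatives(st, p)
  # activation gates below their depolarized steady state must open
  for (g in c("m", "oa", "ua", "d")) expect_gt(d$dy[[g]], 0)
  # inactivation gates near 1 must close at 0 mV
  for (g in c("h", "j", "oi", "f")) expect_lt(d$dy[[g]], 0)
})

test_that("with g_K2P = 0 the K2P current drops out of the balance", {
  p <- crn_params("SR")
  p["g_k2p"] <- 0
  st <- settled_sr_state()
  d <- cell_derivatives(st, p)
  expect_identical(d$currents[["i_k2p"]], 0)
  # and the voltage derivative equals minus the sum of the other currents
  expect_equal(d$dy[["vm"]], -sum(d$currents), tolerance = 1e-12)
})

test_that("paced APD90 converges under step refinement and adapts to rate", {
  p <- crn_params("SR")
  st <- settled_sr_state()
  apd_at <- function(cl, dt) {
    stim <- stimulus_spec(cycle_length = cl, n_beats = 12)
    tr <- integrate_cell(st, p, stim, duration = 12 * cl, dt = dt,
                         sample_dt = 0.1, record_from = 11 * cl)
    extract_biomarkers(tr, stim_onset = 11 * cl + 10)$apd90
  }
  a_coarse <- apd_at(1000, 0.02)
  a_half <- apd_at(1000, 0.01)
  a_ref <- apd_at(1000, 0.002)
  expect_lt(abs(a_coarse - a_half), 1)             # halving dt: < 1 ms
  expect_lt(abs(a_coarse - a_ref) / a_ref, 0.15)   # vs fine-step reference
  expect_lt(apd_at(500, 0.02), a_coarse)           # APD90(2 Hz) < APD90(1 Hz)
})

test_that("gates stay in [0,1] across scaled models and increasing g_K2P shortens APD", {
  st <- settled_sr_state()
  apds <- c()
  for (s in c(0.5, 1.0, 1.5)) {
    p <- crn_params("SR")
    p["g_k2p"] <- p["g_k2p"] * s
    stim <- stimulus_spec(cycle_length = 1000, n_beats = 8)
    tr <- integrate_cell(st, p, stim, duration = 8000, dt = 0.02,
                         sample_dt = 0.1, record_from = 7000)
    gates <- tr$state[2:16]
    expect_true(all(gates >= 0 & gates <= 1))
    apds <- c(apds, extract_biomarkers(tr, 7010)$apd90)
  }
  expect_true(all(diff(apds) < 0))
})

test_that("random conductance scalings keep the state admissible", {
  set.seed(42)
  st <- settled_sr_state()
  for (k in 1:3) {
    sc <- runif(8, 0.5, 1.5)
    p <- apply_scaling(crn_params("SR"), sc)
    stim <- stimulus_spec(cycle_length = 600, n_beats = 5)
    tr <- integrate_cell(st, p, stim, duration = 3000, dt = 0.02,
                         sample_dt = 1)
    expect_true(all(tr$state[2:16] >= 0 & tr$state[2:16] <= 1))
    expect_true(all(tr$state[17:21] > 0))
  }
})

test_that("parameter JSON round-trip is exact and invalid input errors", {
  p <- crn_params("AF")
  f <- tempfile(fileext = ".json")
  write_params_json(p, f)
  expect_equal(read_params_json(f), p)
  bad <- crn_initial_state(); bad["m"] <- 2
  expect_error(integrate_cell(bad, p, NULL, 100), "\\[0, 1\\]")
  expect_error(integrate_cell(crn_initial_state(), p, NULL, 100, dt = 0.05),
               "dt")
})
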