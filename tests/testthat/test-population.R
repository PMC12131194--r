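test_that("LHS stratification holds exhaustively for every column", {
  m <- lhs_sample(100, 8, seed = 5)
  expect_equal(dim(m), c(100, 8))
  for (j in 1:8) {
    v <- sort(m[, j])
    k <- seq_len(100)
    expect_true(all(v >= 0.5 + (k - 1) * 0.01 & v < 0.5 + k * 0.01))
  }
  # determinism and single-vector case
  expect_identical(lhs_sample(100, 8, seed = 5), m)
  one <- lhs_sample(1, 8, seed = 2)
  expect_true(all(one >= 0.5 & one <= 1.5))
  expect_error(lhs_sample(10, 8, lo = 2, hi = 1), "lo")
})

test_that("biomarkers of an analytic triangle AP are exact", {
  tr <- triangle_trace()
  b <- extract_biomarkers(tr, stim_onset = 10)
  expect_true(b$has_ap)
  expect_equal(b$rmp, -80)
  expect_equal(b$apa, 100)
  expect_equal(b$apd50, 100, tolerance = 0.02)
  expect_equal(b$apd90, 180, tolerance = 0.02)
})

test_that("a flat trace is flagged as no AP, not an error", {
  flat <- list(time = 0:300, vm = rep(-80, 301))
  b <- extract_biomarkers(flat, stim_onset = 10)
  expect_false(b$has_ap)
  expect_true(is.na(b$apd90))
})

test_that("biomarker extraction is invariant to uniform time shifts", {
  tr <- triangle_trace(dt = 0.5)
  sh <- list(time = tr$time + 137.25, vm = tr$vm)
  b1 <- extract_biomarkers(tr, 10)
  b2 <- extract_biomarkers(sh, 10 + 137.25)
  for (nm in c("apd50", "apd90", "apa", "dvdt_max", "rmp")) {
    expect_equal(b1[[nm]], b2[[nm]])
  }
})

test_that("steady-state pacing honors its convergence contract", {
  p <- crn_params("AF")
  st <- settled_af_state()
  # vacuous tolerance: returns after two beats, converged
  quick <- pace_to_steady(p, 1000, max_beats = 10, tol = Inf, state0 = st)
  expect_true(quick$converged)
  expect_equal(quick$beats, 2)
  full <- pace_to_steady(p, 1000, max_beats = 100, tol = 1, state0 = st)
  expect_true(full$converged)
  expect_lt(full$beats, 100)
  b <- full$biomarkers
  expect_lt(b$apd50, b$apd90)
  expect_gt(b$rmp, -88); expect_lt(b$rmp, -75)
  # more beats do not move the converged APD90 by more than tol
  more <- pace_to_steady(p, 1000, max_beats = 2 * full$beats, tol = 1,
                         state0 = st)
  expect_lt(abs(more$biomarkers$apd90 - b$apd90), 1 + 1e-9)
})

test_that("range acceptance matches hand enumeration on a 10-row fixture", {
  bm <- data.frame(
    apd50 = c(60, 60, 10, 60, 60, 60, 60, 60, 60, NA),
    apd90 = c(150, 260, 150, 150, 150, 150, 150, 89, 250, 150),
    apa = c(100, 100, 100, 80, 100, 100, 100, 100, 100, 100),
    dvdt_max = c(150, 150, 150, 150, 90, 150, 150, 150, 150, 150),
    rmp = c(-80, -80, -80, -80, -80, -70, -80, -80, -80, -80))
  r <- calibration_ranges("AF")
  # hand enumeration: rows 1 and 7 pass every interval; 9 passes apd90 at
  # the boundary; the rest each violate exactly one biomarker (or are NA)
  expect_identical(biomarkers_within(bm, r),
                   c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE,
                     TRUE, FALSE))
})

test_that("acceptance is monotone: widening a range never shrinks the set", {
  set.seed(8)
  bm <- data.frame(apd50 = runif(50, 0, 200), apd90 = runif(50, 50, 350),
                   apa = runif(50, 60, 140), dvdt_max = runif(50, 50, 350),
                   rmp = runif(50, -95, -60))
  narrow <- calibration_ranges("AF")
  wide <- calibration_ranges("AF",
    override = list(apd90 = c(50, 400), rmp = c(-100, -50)))
  a_n <- biomarkers_within(bm, narrow)
  a_w <- biomarkers_within(bm, wide)
  expect_true(all(a_w[a_n]))
})

test_that("packaged phenotype ranges encode AF shortening and validate", {
  sr <- calibration_ranges("SR"); af <- calibration_ranges("AF")
  expect_lt(af$apd90[2], sr$apd90[2])
  for (r in c(sr, af)) expect_lt(r[1], r[2])
  o <- calibration_ranges("AF", override = list(apa = c(10, 20)))
  expect_equal(o$apa, c(10, 20))
  expect_error(calibration_ranges("AF", override = list(apa = c(5, 2))),
               "invalid interval")
  expect_error(calibration_ranges("XX"))
})

test_that("calibration accepts all under infinite ranges and none under impossible ones", {
  scal <- lhs_sample(4, 8, seed = 3)
  st <- settled_af_state()
  inf_r <- calibration_ranges("AF", override = list(
    apd50 = c(0, Inf), apd90 = c(0, Inf), apa = c(0, Inf),
    dvdt_max = c(0, Inf), rmp = c(-Inf, 0)))
  cal <- calibrate_population(scal, inf_r, state0 = st, max_beats = 20)
  expect_true(all(cal$accepted))
  none_r <- calibration_ranges("AF", override = list(apd90 = c(0.1, 0.2)))
  cal0 <- calibrate_population(scal, none_r, state0 = st, max_beats = 20)
  expect_false(any(cal0$accepted))
  expect_true(all(grepl("apd90", cal0$audit$rejection_reason)))
})

test_that("accepted-model APD90 falls with the G_K2P stratum", {
  pop <- af_trial_population()
  cal <- pop$calibration
  ok <- cal$accepted
  gk <- cal$scalings[ok, "G_K2P"]
  apd <- cal$biomarkers$apd90[ok]
  lowhalf <- gk <= stats::median(gk)
  expect_gt(mean(apd[lowhalf]), mean(apd[!lowhalf]))
})
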