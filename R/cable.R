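#' Configuration of the 1D monodomain cable
#'
#' A homogeneous strand of atrial cells with zero-flux ends. Defaults: 100
#' cells at dx = 0.02 cm (2 cm strand), stimulus into cells 1-3, conduction
#' velocity measured between cells 26 and 76 (1 cm apart), distal success
#' electrode at cell 96 - geometry chosen so boundary effects are
#' negligible at the 80 cm/s bulk-tissue velocity target.
#'
#' @param n_cells Number of cells (>= 20).
#' @param dx Internode spacing (cm).
#' @param diff_coef Diffusion coefficient (cm^2/ms).
#' @param stim_cells Range (1-based, contiguous) of stimulated cells.
#' @param cv_cells Two cell indices between which CV is measured.
#' @param distal_cell Electrode used for propagation success.
#' @return A `cable_config` list.
#' @export
cable_config <- function(n_cells = 100, dx = 0.02, diff_coef = 1e-3,
                         stim_cells = 1:3, cv_cells = c(26, 76),
                         distal_cell = 96) {
  if (n_cells < 20) stop("n_cells must be >= 20")
  if (dx <= 0 || diff_coef <= 0) stop("dx and diff_coef must be positive")
  idx <- c(stim_cells, cv_cells, distal_cell)
  if (any(idx < 1 | idx > n_cells)) stop("cell index out of bounds")
  structure(list(n_cells = n_cells, dx = dx, diff_coef = diff_coef,
                 stim_cells = range(stim_cells), cv_cells = cv_cells,
                 distal_cell = distal_cell),
            class = "cable_config")
}

#' Solve the monodomain cable
#'
#' Finite-difference monodomain `Cm dV/dt = D d2V/dx2 - I_ion + I_stim`
#' with zero-flux ends, Strang splitting (half diffusion, reaction, half
#' diffusion) and the single-cell kernel per node. Refuses to run if the
#' diffusion stability bound `D dt / dx^2 <= 0.5` fails. Activation time
#' per cell is the instant of maximum dV/dt during its upstroke.
#'
#' @param config A [cable_config()].
#' @param params Parameter vector filling the whole (homogeneous) strand.
#' @param stim_starts Stimulus onset times (ms).
#' @param duration Simulated time (ms).
#' @param dt Step (ms).
#' @param state0 Either a 21-vector replicated across cells, or a
#'   `21 x n_cells` matrix; settled baseline state by default.
#' @param stim_amplitude,stim_duration Pulse parameters (pA/pF, ms).
#' @param record_cells Cells whose Vm traces to keep (1-based).
#' @param sample_dt Trace sampling interval (ms).
#' @param reaction If FALSE the ionic model is switched off (pure
#'   diffusion), for conservation checks.
#' @return List with `activations` (list of activation-time vectors, one
#'   per cell), `time`, `traces`, `state` (final 21 x n matrix).
#' @export
solve_cable <- function(config, params, stim_starts, duration, dt = 0.02,
                        state0 = NULL, stim_amplitude = 64,
                        stim_duration = 2, record_cells = integer(0),
                        sample_dt = 1, reaction = TRUE) {
  params <- .check_params(params)
  if (config$diff_coef * dt / config$dx^2 > 0.5) {
    stop(sprintf("unstable configuration: D*dt/dx^2 = %.3f > 0.5",
                 config$diff_coef * dt / config$dx^2))
  }
  if (is.null(state0)) state0 <- crn_initial_state()
  if (is.null(dim(state0))) {
    state0 <- matrix(state0, nrow = 21, ncol = config$n_cells)
  }
  out <- cable_integrate_cpp(state0, as.numeric(params),
                             config$diff_coef, config$dx, duration, dt,
                             stim_starts, stim_duration, stim_amplitude,
                             config$stim_cells[1] - 1L,
                             config$stim_cells[2] - 1L,
                             as.integer(record_cells) - 1L,
                             sample_dt, 0, reaction)
  if (isTRUE(out$aborted)) {
    stop(sprintf("cable integration unstable at t = %.2f ms", out$abort_time))
  }
  out
}

#' Planar-wave conduction velocity between two cable cells
#'
#' `CV = (x2 - x1) * dx / (t2 - t1)` from the first activation of each
#' cell, reported in cm/s. A missing activation marks conduction block:
#' the return value is NA with attribute `conduction_block = TRUE`.
#'
#' @param activations Activation list from [solve_cable()].
#' @param config The cable configuration.
#' @param cells Two cell indices (defaults to `config$cv_cells`).
#' @return CV in cm/s (or NA on block).
#' @export
measure_cv <- function(activations, config, cells = config$cv_cells) {
  a1 <- activations[[cells[1]]]
  a2 <- activations[[cells[2]]]
  if (length(a1) == 0 || length(a2) == 0) {
    return(structure(NA_real_, conduction_block = TRUE))
  }
  t1 <- a1[1]; t2 <- a2[1]
  if (t2 == t1) stop("equal activation times: unphysical CV")
  (cells[2] - cells[1]) * config$dx / (t2 - t1) * 1000
}

.cable_settled_state <- function(params, dt = 0.02, settle_ms = 20000) {
  settle_cell(params, duration = settle_ms, dt = dt)
}

.cv_once <- function(config, params, diff_coef, state, dt,
                     cycle_length = 500, n_beats = 2) {
  cfg <- config; cfg$diff_coef <- diff_coef
  starts <- 10 + cycle_length * (seq_len(n_beats) - 1)
  dur <- max(starts) + 250
  out <- solve_cable(cfg, params, starts, dur, dt = dt, state0 = state)
  # CV from the last delivered beat
  last <- max(starts)
  act <- lapply(out$activations, function(a) a[a >= last])
  measure_cv(act, cfg)
}

#' Calibrate the cable diffusion coefficient to a CV target
#'
#' Bisection on D until the measured planar CV matches `target_cv` within
#' `tol`, using 2 Hz pacing and the configured measurement electrodes.
#' Monotonicity of CV in D over the bracket is asserted.
#'
#' @param params Parameter vector.
#' @param target_cv Target velocity (cm/s); 80 cm/s bulk-tissue default.
#' @param tol Acceptance tolerance (cm/s).
#' @param config Cable configuration.
#' @param bracket Initial D bracket (cm^2/ms), expanded if needed.
#' @param dt Step (ms).
#' @param max_iter Bisection budget.
#' @return List with `diff_coef`, `cv` (final measured CV), `iterations`.
#' @export
calibrate_diffusion <- function(params, target_cv = 80, tol = 1,
                                config = cable_config(),
                                bracket = c(2e-4, 4e-3), dt = 0.02,
                                max_iter = 40) {
  params <- .check_params(params)
  state <- .cable_settled_state(params, dt = dt)
  f <- function(D) .cv_once(config, params, D, state, dt)
  lo <- bracket[1]; hi <- bracket[2]
  cv_lo <- f(lo); cv_hi <- f(hi)
  tries <- 0
  while ((is.na(cv_lo) || cv_lo > target_cv) && tries < 4) {
    lo <- lo / 4; cv_lo <- f(lo); tries <- tries + 1
  }
  while ((!is.na(cv_hi) && cv_hi < target_cv) && tries < 8) {
    hi <- hi * 4; cv_hi <- f(hi); tries <- tries + 1
  }
  if (is.na(cv_hi) || cv_hi < target_cv || (!is.na(cv_lo) && cv_lo > target_cv)) {
    stop(sprintf("cannot bracket target CV %.1f cm/s: CV(%.2e) = %.1f, CV(%.2e) = %.1f",
                 target_cv, lo, ifelse(is.na(cv_lo), NaN, cv_lo),
                 hi, cv_hi))
  }
  if (!is.na(cv_lo) && cv_lo >= cv_hi) {
    stop("CV is not increasing in D over the bracket")
  }
  cv_mid <- NA_real_; mid <- NA_real_
  for (it in seq_len(max_iter)) {
    mid <- sqrt(lo * hi)          # geometric bisection: CV ~ sqrt(D)
    cv_mid <- f(mid)
    if (!is.na(cv_mid) && abs(cv_mid - target_cv) < tol) {
      return(list(diff_coef = mid, cv = cv_mid, iterations = it))
    }
    if (is.na(cv_mid) || cv_mid < target_cv) lo <- mid else hi <- mid
  }
  stop(sprintf("no convergence after %d iterations (last CV %.2f)",
               max_iter, cv_mid))
}

# S2 counts as propagated when the distal electrode fires once more than in
# an S1-only reference run from the same state (robust to slow conduction,
# where the final S1 wavefront itself arrives late at the electrode)
.s2_propagates <- function(config, params, state_s1, ci, dt,
                           stim_amplitude, stim_duration, n_ref,
                           window = 300) {
  dur <- ci + window
  out <- solve_cable(config, params, c(0, ci), dur, dt = dt,
                     state0 = state_s1, stim_amplitude = stim_amplitude,
                     stim_duration = stim_duration)
  length(out$activations[[config$distal_cell]]) > n_ref
}

#' S1-S2 protocol description
#'
#' @param s1_cl S1 cycle length (ms); 500 ms (2 Hz).
#' @param n_s1 Number of S1 beats before the premature S2.
#' @param s2_bounds Search bounds for the S1-S2 coupling interval (ms).
#' @param resolution Coupling-interval resolution (ms).
#' @return An `s1s2_protocol` list.
#' @export
s1s2_protocol <- function(s1_cl = 500, n_s1 = 10, s2_bounds = c(40, 500),
                          resolution = 1) {
  if (s2_bounds[1] >= s2_bounds[2]) stop("s2 bounds must be ordered")
  if (resolution <= 0) stop("resolution must be positive")
  structure(list(s1_cl = s1_cl, n_s1 = n_s1, s2_bounds = s2_bounds,
                 resolution = resolution),
            class = "s1s2_protocol")
}

#' Effective refractory period on the cable
#'
#' ERP = shortest S1-S2 coupling interval whose S2 beat propagates to the
#' distal electrode, located by binary search at the protocol resolution
#' after an S1 train at the protocol cycle length. The S1 train state is
#' computed once and reused for every S2 probe. Captures post-
#' repolarization refractoriness: under strong I_Na block the ERP exceeds
#' the APD.
#'
#' @param params Parameter vector.
#' @param config Cable configuration (with calibrated `diff_coef`).
#' @param protocol An [s1s2_protocol()].
#' @param dt Step (ms).
#' @param stim_amplitude,stim_duration Pulse parameters.
#' @param search "binary" (default) or "linear" (exhaustive scan oracle).
#' @return List with `erp_ms`, `s1_captured` flag, `no_block_at_min` /
#'   `block_at_max` flags for degenerate outcomes.
#' @export
measure_erp <- function(params, config, protocol = s1s2_protocol(),
                        dt = 0.02, stim_amplitude = 64, stim_duration = 2,
                        search = c("binary", "linear")) {
  search <- match.arg(search)
  params <- .check_params(params)
  state <- .cable_settled_state(params, dt = dt)
  starts <- 10 + protocol$s1_cl * (seq_len(protocol$n_s1) - 1)
  t_last <- max(starts)
  train <- solve_cable(config, params, starts, t_last, dt = dt,
                       state0 = state, stim_amplitude = stim_amplitude,
                       stim_duration = stim_duration)
  n_distal <- length(train$activations[[config$distal_cell]])
  # run the final S1 alone from the saved state as the reference
  state_s1 <- train$state
  ref <- solve_cable(config, params, 0,
                     protocol$s2_bounds[2] + 300, dt = dt,
                     state0 = state_s1, stim_amplitude = stim_amplitude,
                     stim_duration = stim_duration)
  n_ref <- length(ref$activations[[config$distal_cell]])
  s1_captured <- (n_distal == protocol$n_s1 - 1) && n_ref >= 1
  prop <- function(ci) .s2_propagates(config, params, state_s1, ci, dt,
                                      stim_amplitude, stim_duration, n_ref)
  lo <- protocol$s2_bounds[1]; hi <- protocol$s2_bounds[2]
  res <- protocol$resolution
  if (search == "linear") {
    for (ci in seq(lo, hi, by = res)) {
      if (prop(ci)) {
        return(list(erp_ms = ci, s1_captured = s1_captured,
                    no_block_at_min = ci == lo, block_at_max = FALSE))
      }
    }
    return(list(erp_ms = NA_real_, s1_captured = s1_captured,
                no_block_at_min = FALSE, block_at_max = TRUE))
  }
  if (prop(lo)) {
    return(list(erp_ms = lo, s1_captured = s1_captured,
                no_block_at_min = TRUE, block_at_max = FALSE))
  }
  if (!prop(hi)) {
    return(list(erp_ms = NA_real_, s1_captured = s1_captured,
                no_block_at_min = FALSE, block_at_max = TRUE))
  }
  while (hi - lo > res) {
    mid <- lo + res * floor((hi - lo) / (2 * res))
    if (mid <= lo) mid <- lo + res
    if (prop(mid)) hi <- mid else lo <- mid
  }
  list(erp_ms = hi, s1_captured = s1_captured,
       no_block_at_min = FALSE, block_at_max = FALSE)
}

#' 1:1 propagation check at a pacing rate
#'
#' Delivers a preconditioning drive of `n_pre` pulses at the test rate
#' (letting APD rate-adapt to its steady state), then `n_stimuli`
#' assessment pulses, and reports whether every assessment stimulus
#' propagated to the distal electrode (1:1 capture). Conduction block is
#' a result, not an error.
#'
#' @param params Parameter vector.
#' @param config Cable configuration.
#' @param rate Pacing rate (Hz).
#' @param n_stimuli Number of assessment pulses.
#' @param n_pre Preconditioning pulses at the same rate.
#' @param dt Step (ms).
#' @param stim_amplitude,stim_duration Pulse parameters.
#' @return List with `captures` (distal activations during the assessment
#'   window, capped at `n_stimuli`) and `success` flag.
#' @export
propagation_check <- function(params, config, rate, n_stimuli = 10,
                              n_pre = 10, dt = 0.02, stim_amplitude = 64,
                              stim_duration = 2) {
  if (rate <= 0) stop("rate must be positive")
  params <- .check_params(params)
  cl <- 1000 / rate
  state <- .cable_settled_state(params, dt = dt)
  starts <- 10 + cl * (seq_len(n_pre + n_stimuli) - 1)
  t_assess <- 10 + cl * n_pre      # first assessment stimulus
  out <- solve_cable(config, params, starts, max(starts) + cl, dt = dt,
                     state0 = state, stim_amplitude = stim_amplitude,
                     stim_duration = stim_duration)
  act <- out$activations[[config$distal_cell]]
  captures <- min(sum(act >= t_assess), n_stimuli)
  list(captures = captures, success = captures == n_stimuli)
}
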