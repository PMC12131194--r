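#' @useDynLib afsilico, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# parameter vector order shared with the compiled kernel
.par_names <- c("g_na", "g_k1", "g_to", "g_kr", "g_ks", "g_cal", "g_kur",
                "g_bna", "g_bca", "i_nak_max", "i_naca_max", "i_pca_max",
                "g_k2p", "k_o", "na_o", "ca_o", "cm")

.state_names <- c("vm", "m", "h", "j", "oa", "oi", "ua", "ui", "xr", "xs",
                  "d", "f", "f_ca", "u", "v", "w",
                  "na_i", "k_i", "ca_i", "ca_up", "ca_rel")

# conductances the population sampler and the drug model may scale
.scaled_names <- c("G_Kur", "G_Kr", "G_to", "G_K1", "G_CaL", "G_Na",
                   "G_NaK", "G_K2P")
.scaled_par <- c(G_Kur = "g_kur", G_Kr = "g_kr", G_to = "g_to",
                 G_K1 = "g_k1", G_CaL = "g_cal", G_Na = "g_na",
                 G_NaK = "i_nak_max", G_K2P = "g_k2p")

#' Baseline model parameters for the atrial cardiomyocyte model
#'
#' Returns the maximal conductances, pump/exchanger rates and external ion
#' concentrations of the Courtemanche-Ramirez-Nattel (CRN) human atrial
#' cardiomyocyte model, extended with the chord conductance `g_k2p` of a
#' TASK-1-type two-pore-domain background K+ current. Units: conductances in
#' nS/pF, pump currents in pA/pF, concentrations in mM, capacitance in pF.
#'
#' With `phenotype = "AF"` the baseline is remodeled towards chronic atrial
#' fibrillation before any population scaling: reduced I_to and I_CaL,
#' increased I_K1, and an upregulated TASK-1 current, the combination that
#' shortens the atrial action potential in persistent AF.
#'
#' @param phenotype "SR" (sinus rhythm, unremodeled) or "AF"
#'   (chronic-AF-remodeled).
#' @return Named numeric vector of model parameters.
#' @export
crn_params <- function(phenotype = c("SR", "AF")) {
  phenotype <- match.arg(phenotype)
  p <- c(g_na = 7.8, g_k1 = 0.09, g_to = 0.1652, g_kr = 0.029411765,
         g_ks = 0.12941176, g_cal = 0.12375, g_kur = 1.0,
         g_bna = 0.0006744375, g_bca = 0.001131,
         i_nak_max = 0.59933874, i_naca_max = 1600, i_pca_max = 0.275,
         g_k2p = 0.002, k_o = 5.4, na_o = 140, ca_o = 1.8, cm = 100)
  if (phenotype == "AF") {
    # chronic-AF electrical remodeling of the human atrium: I_to -50%,
    # I_CaL -40%, I_K1 +75%, I_Kur -45%, TASK-1 (I_K2P) doubled
    p["g_to"]  <- p["g_to"] * 0.50
    p["g_cal"] <- p["g_cal"] * 0.60
    p["g_k1"]  <- p["g_k1"] * 1.75
    p["g_kur"] <- p["g_kur"] * 0.55
    p["g_k2p"] <- p["g_k2p"] * 2.0
  }
  p
}

#' Published resting state of the CRN model
#'
#' Initial conditions as published for the CRN model: resting membrane
#' voltage, 15 gating variables and 5 ionic concentrations.
#'
#' @return Named numeric vector (21 entries).
#' @export
crn_initial_state <- function() {
  c(vm = -81.18, m = 2.908e-3, h = 9.649e-1, j = 9.775e-1,
    oa = 3.043e-2, oi = 9.992e-1, ua = 4.966e-3, ui = 9.986e-1,
    xr = 3.296e-5, xs = 1.869e-2, d = 1.367e-4, f = 9.996e-1,
    f_ca = 7.755e-1, u = 0.0, v = 1.0, w = 9.992e-1,
    na_i = 11.17, k_i = 139.0, ca_i = 1.013e-4,
    ca_up = 1.488, ca_rel = 1.488)
}

.check_state <- function(state) {
  if (length(state) != 21L) stop("state must have 21 entries")
  gates <- state[2:16]
  if (any(gates < -1e-9 | gates > 1 + 1e-9)) stop("gating variables must lie in [0, 1]")
  if (any(state[17:21] <= 0)) stop("ionic concentrations must be positive")
  if (!is.finite(state[1])) stop("membrane voltage must be finite")
  invisible(state)
}

.check_params <- function(params) {
  if (length(params) != length(.par_names)) {
    stop("params must have ", length(.par_names), " entries (see crn_params())")
  }
  if (!is.null(names(params)) && !identical(names(params), .par_names)) {
    params <- params[.par_names]
  }
  if (any(!is.finite(params))) stop("non-finite model parameter")
  if (any(params[1:13] < 0)) stop("conductances and pump rates must be >= 0")
  params
}

#' TASK-1 (K2P) background potassium current
#'
#' Open, GHK-type outwardly rectifying background K+ current
#' `I = g_k2p * f(vm, k_o, k_i) * (vm - E_K)`, where `E_K` is the Nernst
#' potential and `f` the Goldman-Hodgkin-Katz chord-rectification factor
#' normalized so that `g_k2p` is the chord conductance at 0 mV.
#'
#' @param vm Membrane voltage (mV).
#' @param k_o,k_i Extra-/intracellular K+ (mM), both positive.
#' @param g_k2p Chord conductance at 0 mV (nS/pF).
#' @return Current in pA/pF (positive = outward).
#' @export
ik2p_current <- function(vm, k_o, k_i, g_k2p) {
  if (any(k_o <= 0) || any(k_i <= 0)) {
    stop("potassium concentrations must be positive")
  }
  n <- max(length(vm), length(k_o), length(k_i), length(g_k2p))
  vm <- rep_len(vm, n); k_o <- rep_len(k_o, n)
  k_i <- rep_len(k_i, n); g_k2p <- rep_len(g_k2p, n)
  vapply(seq_len(n), function(i) {
    ik2p_current_cpp(vm[i], k_o[i], k_i[i], g_k2p[i])
  }, numeric(1))
}

#' Apply multiplicative conductance scaling factors
#'
#' Multiplies the eight varied maximal conductances/fluxes
#' (G_Kur, G_Kr, G_to, G_K1, G_CaL, G_Na, G_NaK, G_K2P) by the entries of a
#' scaling vector, leaving everything else untouched.
#'
#' @param params Parameter vector from [crn_params()].
#' @param scaling Named (or positionally ordered) numeric vector of 8 factors
#'   for G_Kur, G_Kr, G_to, G_K1, G_CaL, G_Na, G_NaK, G_K2P.
#' @return Scaled parameter vector.
#' @export
apply_scaling <- function(params, scaling) {
  params <- .check_params(params)
  if (length(scaling) != 8L) stop("scaling must have 8 entries")
  if (is.null(names(scaling))) names(scaling) <- .scaled_names
  for (nm in names(scaling)) {
    tgt <- .scaled_par[[nm]]
    if (is.null(tgt)) stop("unknown scaling target: ", nm)
    params[[tgt]] <- params[[tgt]] * scaling[[nm]]
  }
  params
}

#' Stimulus specification for pacing protocols
#'
#' @param amplitude Depolarizing current amplitude (pA/pF, positive
#'   depolarizes). The default is twice the diastolic threshold of the
#'   baseline model for a 2 ms pulse.
#' @param duration Pulse width (ms).
#' @param cycle_length Pacing cycle length (ms).
#' @param n_beats Number of pulses.
#' @param start Time of the first pulse (ms).
#' @return A `stimulus_spec` list.
#' @export
stimulus_spec <- function(amplitude = 22, duration = 2, cycle_length = 1000,
                          n_beats = 1, start = 10) {
  if (duration >= cycle_length) stop("stimulus duration must be < cycle length")
  if (n_beats < 1) stop("n_beats must be >= 1")
  structure(list(amplitude = amplitude, duration = duration,
                 cycle_length = cycle_length, n_beats = n_beats,
                 start = start),
            class = "stimulus_spec")
}

.stim_starts <- function(stim) {
  stim$start + stim$cycle_length * (seq_len(stim$n_beats) - 1)
}

#' Time derivatives of the full cell state
#'
#' Right-hand side of the CRN + I_K2P model:
#' `dV/dt = -(sum(I_ion) + I_stim) / C_m` with all membrane currents in
#' pA/pF (capacitance-normalized), Hodgkin-Huxley gate relaxation towards
#' voltage-dependent steady states, and the CRN Ca2+ handling fluxes.
#'
#' @param state Named state vector as from [crn_initial_state()].
#' @param params Parameter vector from [crn_params()] (possibly scaled).
#' @param i_stim Stimulus current (pA/pF; the sign convention used here is
#'   the raw current entering the balance, so a depolarizing pulse of
#'   amplitude A is `i_stim = -A`).
#' @return List with `dy` (named derivative vector) and `currents`
#'   (named vector of the individual membrane currents, pA/pF).
#' @export
cell_derivatives <- function(state, params, i_stim = 0) {
  state <- .check_state(state)
  params <- .check_params(params)
  if (any(!is.finite(state))) stop("non-finite state value")
  out <- crn_rhs_cpp(as.numeric(state), as.numeric(params), i_stim)
  names(out$dy) <- .state_names
  out
}

#' Integrate the single-cell model under a pacing protocol
#'
#' Fixed-step integration (Rush-Larsen for gates, forward Euler for voltage
#' and concentrations). Aborts with an error if |Vm| exceeds 200 mV.
#'
#' @param state0 Initial state vector.
#' @param params Parameter vector.
#' @param stim A [stimulus_spec()] or NULL for an unstimulated run.
#' @param duration Total simulated time (ms).
#' @param dt Integration step (ms), capped at 0.02.
#' @param sample_dt Output sampling interval (ms).
#' @param record_from Discard output before this time (ms).
#' @return A `trace` object: list with `time`, `vm` (sampled), `state`
#'   (final full state), `dt`, `sample_dt`.
#' @export
integrate_cell <- function(state0, params, stim = NULL, duration,
                           dt = 0.01, sample_dt = 0.1, record_from = 0) {
  state0 <- .check_state(state0)
  params <- .check_params(params)
  if (dt > 0.02) stop("dt must be <= 0.02 ms")
  if (is.null(stim)) {
    starts <- numeric(0); sdur <- 0; samp <- 0
  } else {
    starts <- .stim_starts(stim); sdur <- stim$duration; samp <- stim$amplitude
    if (duration < max(starts) + sdur) {
      stop("duration does not cover the stimulus protocol")
    }
  }
  out <- crn_integrate_cpp(as.numeric(state0), as.numeric(params),
                           duration, dt, starts, sdur, samp,
                           sample_dt, record_from)
  if (isTRUE(out$aborted)) {
    stop(sprintf("integration unstable (|vm| > 200 mV) at t = %.3f ms",
                 out$abort_time))
  }
  names(out$state) <- .state_names
  structure(list(time = out$time, vm = out$vm, state = out$state,
                 dt = dt, sample_dt = sample_dt),
            class = "trace")
}

#' Let the unstimulated model settle to its resting state
#'
#' @param params Parameter vector.
#' @param duration Settling time (ms); 60000 ms default.
#' @param state0 Starting state (published resting state by default).
#' @param dt Integration step (ms).
#' @return Final state vector.
#' @export
settle_cell <- function(params, duration = 60000, state0 = crn_initial_state(),
                        dt = 0.02) {
  tr <- integrate_cell(state0, params, stim = NULL, duration = duration,
                       dt = dt, sample_dt = duration / 2,
                       record_from = duration)
  tr$state
}

#' Diastolic stimulus threshold by doubling search plus bisection
#'
#' Finds the minimal 2 ms pulse amplitude that elicits an action potential
#' (peak Vm > 0 mV) from the resting state, to a relative precision of ~2%.
#'
#' @param params Parameter vector.
#' @param state0 Resting state to stimulate from.
#' @param duration Pulse width (ms).
#' @param dt Integration step (ms).
#' @return Threshold amplitude (pA/pF).
#' @export
find_stim_threshold <- function(params, state0 = NULL, duration = 2,
                                dt = 0.02) {
  if (is.null(state0)) state0 <- settle_cell(params, duration = 20000, dt = dt)
  fires <- function(amp) {
    st <- stimulus_spec(amplitude = amp, duration = duration,
                        cycle_length = 400, n_beats = 1, start = 5)
    tr <- integrate_cell(state0, params, st, duration = 300, dt = dt,
                         sample_dt = 0.5)
    max(tr$vm) > 0
  }
  lo <- 0; hi <- 2
  while (!fires(hi)) {
    lo <- hi; hi <- hi * 2
    if (hi > 512) stop("no capture up to 512 pA/pF")
  }
  while ((hi - lo) / hi > 0.02) {
    mid <- (lo + hi) / 2
    if (fires(mid)) hi <- mid else lo <- mid
  }
  hi
}

#' Export a voltage trace as CSV
#'
#' @param trace A `trace` from [integrate_cell()].
#' @param path Output file.
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(data.frame(time_ms = trace$time, vm_mV = trace$vm),
                   path, row.names = FALSE)
}

#' Round-trip model parameters through JSON
#'
#' @param params Named parameter vector.
#' @param path File path.
#' @export
write_params_json <- function(params, path) {
  jsonlite::write_json(as.list(params), path, auto_unbox = TRUE, digits = NA)
}

#' @rdname write_params_json
#' @export
read_params_json <- function(path) {
  unlist(jsonlite::read_json(path, simplifyVector = TRUE))[.par_names]
}
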