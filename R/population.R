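#' Latin Hypercube sample of conductance scaling factors
#'
#' Draws `n` scaling vectors over `d` conductance dimensions with one value
#' in each of `n` equal-width strata of `[lo, hi]` per column (maximin not
#' required; plain stratified LHS). Reproducible for a fixed seed.
#'
#' @param n Number of models.
#' @param d Number of scaled conductances (8 for the atrial population).
#' @param lo,hi Scaling bounds (0.5 and 1.5: +-50% variation).
#' @param seed Integer seed.
#' @return `n x d` matrix; columns named after the scaled conductances when
#'   `d == 8`.
#' @export
lhs_sample <- function(n, d = 8, lo = 0.5, hi = 1.5, seed = 1) {
  if (n < 1 || d < 1) stop("n and d must be >= 1")
  if (lo >= hi) stop("lo must be < hi")
  set.seed(seed)
  m <- lhs::randomLHS(n, d)
  m <- lo + (hi - lo) * m
  if (d == 8L) colnames(m) <- .scaled_names
  m
}

#' Extract action-potential biomarkers from a voltage trace
#'
#' Biomarkers of the first complete action potential after `stim_onset`:
#' resting membrane potential (RMP, Vm immediately before the stimulus),
#' AP amplitude (APA, peak minus RMP), maximum upstroke velocity
#' (dV/dt_max, V/s), and APD50/APD90 measured from the instant of
#' dV/dt_max to the first downward crossing of peak minus 50%/90% of APA
#' (linearly interpolated between samples).
#'
#' @param trace A `trace` from [integrate_cell()] (or any list with `time`
#'   and `vm`).
#' @param stim_onset Stimulus time (ms) within the trace.
#' @param dvdt_threshold Minimal upstroke velocity (V/s) below which the
#'   beat is flagged as "no AP" rather than measured.
#' @return List with `apd50`, `apd90` (ms), `apa` (mV), `dvdt_max` (V/s),
#'   `rmp` (mV) and `has_ap` flag. When no AP is detected the numeric
#'   fields are NA and `has_ap` is FALSE.
#' @export
extract_biomarkers <- function(trace, stim_onset, dvdt_threshold = 10) {
  tt <- trace$time; vm <- trace$vm
  pre <- which(tt < stim_onset)
  if (length(pre) == 0) stop("trace does not cover the pre-stimulus interval")
  rmp <- vm[pre[length(pre)]]

  no_ap <- list(apd50 = NA_real_, apd90 = NA_real_, apa = NA_real_,
                dvdt_max = NA_real_, rmp = rmp, has_ap = FALSE)

  # include the last pre-stimulus sample so the upstroke's first segment
  # contributes to the derivative
  post <- seq(pre[length(pre)], length(tt))
  if (length(post) < 3) return(no_ap)
  vpost <- vm[post]; tpost <- tt[post]
  dvdt <- diff(vpost) / diff(tpost)         # mV/ms == V/s
  iup <- which.max(dvdt) + 1L               # end of steepest segment
  if (max(dvdt) < dvdt_threshold) return(no_ap)

  ipk <- which.max(vpost)
  peak <- vpost[ipk]
  apa <- peak - rmp
  if (apa <= 0) return(no_ap)

  t_up <- tpost[iup]
  cross_time <- function(level) {
    idx <- seq(ipk, length(vpost))
    below <- idx[vpost[idx] < level]
    if (length(below) == 0) return(NA_real_)
    i2 <- below[1]
    if (i2 == 1) return(tpost[1])
    i1 <- i2 - 1L
    tpost[i1] + (tpost[i2] - tpost[i1]) *
      (vpost[i1] - level) / (vpost[i1] - vpost[i2])
  }
  apd50 <- cross_time(peak - 0.5 * apa) - t_up
  apd90 <- cross_time(peak - 0.9 * apa) - t_up
  list(apd50 = apd50, apd90 = apd90, apa = apa,
       dvdt_max = max(dvdt), rmp = rmp, has_ap = TRUE)
}

#' Pace a cell model to steady state
#'
#' Delivers beats at a fixed cycle length until APD90 changes by less than
#' `tol` between consecutive beats (or `max_beats` is reached) and returns
#' the last beat. Loss of capture on three consecutive beats flags the
#' result instead of raising.
#'
#' @param params Parameter vector.
#' @param cycle_length Pacing cycle length (ms).
#' @param max_beats Beat budget.
#' @param tol APD90 convergence tolerance (ms).
#' @param state0 Starting state (settled baseline state by default).
#' @param stim_amplitude,stim_duration Stimulus pulse (pA/pF, ms).
#' @param dt Integration step (ms).
#' @param sample_dt Trace sampling interval (ms).
#' @return List with `trace` (last beat), `biomarkers`, `converged`,
#'   `captured`, `beats`.
#' @export
pace_to_steady <- function(params, cycle_length, max_beats = 100, tol = 1,
                           state0 = NULL, stim_amplitude = 22,
                           stim_duration = 2, dt = 0.02, sample_dt = 0.1) {
  params <- .check_params(params)
  if (cycle_length <= stim_duration) {
    stop("cycle length must exceed the stimulus duration")
  }
  if (is.null(state0)) state0 <- crn_initial_state()
  stim <- stimulus_spec(amplitude = stim_amplitude, duration = stim_duration,
                        cycle_length = cycle_length, n_beats = 1, start = 10)
  state <- state0
  prev_apd <- NA_real_
  bm <- NULL; tr <- NULL
  converged <- FALSE
  miss <- 0L
  beats <- 0L
  for (k in seq_len(max_beats)) {
    tr <- integrate_cell(state, params, stim, duration = cycle_length,
                         dt = dt, sample_dt = sample_dt)
    state <- tr$state
    bm <- extract_biomarkers(tr, stim_onset = stim$start)
    beats <- k
    if (!bm$has_ap) {
      miss <- miss + 1L
      if (miss >= 3L) {
        return(list(trace = tr, biomarkers = bm, converged = FALSE,
                    captured = FALSE, beats = beats))
      }
      next
    }
    miss <- 0L
    if (k >= 2 && is.finite(prev_apd) &&
        abs(bm$apd90 - prev_apd) < tol) {
      converged <- TRUE
      break
    }
    prev_apd <- bm$apd90
  }
  list(trace = tr, biomarkers = bm, converged = converged,
       captured = isTRUE(bm$has_ap), beats = beats)
}

#' Emulated human atrial AP biomarker calibration ranges
#'
#' Acceptance intervals for the five AP biomarkers at 1 Hz pacing, per
#' phenotype. These are documented constants emulating human atrial
#' cardiomyocyte measurements in sinus rhythm (SR) and chronic AF (the
#' original patient-derived calibration dataset is not published); every
#' interval can be overridden via `override`.
#'
#' @param phenotype "SR" or "AF".
#' @param override Optional named list of `c(min, max)` intervals replacing
#'   packaged ones (names among apd50, apd90, apa, dvdt_max, rmp).
#' @return List of `c(min, max)` intervals per biomarker.
#' @export
calibration_ranges <- function(phenotype = c("SR", "AF"), override = NULL) {
  phenotype <- match.arg(phenotype)
  r <- switch(phenotype,
    SR = list(apd50 = c(80, 250), apd90 = c(180, 440),
              apa = c(85, 130), dvdt_max = c(100, 300),
              rmp = c(-85, -70)),
    AF = list(apd50 = c(20, 150), apd90 = c(90, 250),
              apa = c(85, 130), dvdt_max = c(100, 300),
              rmp = c(-88, -74)))
  if (!is.null(override)) {
    for (nm in names(override)) {
      if (!nm %in% names(r)) stop("unknown biomarker: ", nm)
      r[[nm]] <- override[[nm]]
    }
  }
  bad <- vapply(r, function(x) x[1] >= x[2], logical(1))
  if (any(bad)) stop("invalid interval (min >= max) for: ",
                     paste(names(r)[bad], collapse = ", "))
  r
}

#' Check biomarker rows against calibration ranges
#'
#' @param biomarkers data.frame with columns apd50, apd90, apa, dvdt_max,
#'   rmp (one row per model; NA rows never pass).
#' @param ranges Ranges from [calibration_ranges()].
#' @return Logical vector: TRUE when every biomarker lies inside its range.
#' @export
biomarkers_within <- function(biomarkers, ranges) {
  ok <- rep(TRUE, nrow(biomarkers))
  for (nm in names(ranges)) {
    x <- biomarkers[[nm]]
    ok <- ok & !is.na(x) & x >= ranges[[nm]][1] & x <= ranges[[nm]][2]
  }
  ok
}

#' Calibrate a sampled population against biomarker ranges
#'
#' Paces every scaling vector to steady state and accepts a model iff all
#' five biomarkers of its steady-state AP lie within the given ranges.
#' An empty acceptance set is a legal outcome.
#'
#' @param scalings `n x 8` scaling matrix from [lhs_sample()].
#' @param ranges Ranges from [calibration_ranges()].
#' @param params_base Baseline parameters the scalings multiply.
#' @param cycle_length Calibration pacing cycle length (ms); 1000 ms.
#' @param state0 Starting state shared by all models (settled baseline).
#' @param max_beats,tol,dt Passed to [pace_to_steady()].
#' @return List with `accepted` (logical vector), `biomarkers`
#'   (data.frame, one row per model), `audit` (data.frame with
#'   model_id, accepted, rejection_reason), `scalings`.
#' @export
calibrate_population <- function(scalings, ranges,
                                 params_base = crn_params("AF"),
                                 cycle_length = 1000, state0 = NULL,
                                 max_beats = 40, tol = 1, dt = 0.02) {
  n <- nrow(scalings)
  if (is.null(state0)) {
    state0 <- settle_cell(params_base, duration = 20000, dt = dt)
  }
  bm_names <- c("apd50", "apd90", "apa", "dvdt_max", "rmp")
  bms <- matrix(NA_real_, n, length(bm_names),
                dimnames = list(NULL, bm_names))
  accepted <- logical(n)
  reason <- character(n)
  for (i in seq_len(n)) {
    p <- apply_scaling(params_base, scalings[i, ])
    res <- pace_to_steady(p, cycle_length, max_beats = max_beats, tol = tol,
                          state0 = state0, dt = dt)
    if (!res$captured) {
      reason[i] <- "no AP"
      next
    }
    b <- res$biomarkers
    bms[i, ] <- unlist(b[bm_names])
    fails <- bm_names[vapply(bm_names, function(nm) {
      b[[nm]] < ranges[[nm]][1] || b[[nm]] > ranges[[nm]][2]
    }, logical(1))]
    if (length(fails) == 0) {
      accepted[i] <- TRUE
      reason[i] <- ""
    } else {
      reason[i] <- paste(fails, collapse = "+")
    }
  }
  list(accepted = accepted,
       biomarkers = as.data.frame(bms),
       audit = data.frame(model_id = seq_len(n), accepted = accepted,
                          rejection_reason = reason),
       scalings = scalings)
}

#' Write a calibrated population as CSV
#'
#' Columns: model_id, the 8 scaling factors, accepted flag, the 5
#' biomarkers and the rejection reason.
#'
#' @param calib Result of [calibrate_population()].
#' @param path File path.
#' @export
write_population_csv <- function(calib, path) {
  out <- cbind(data.frame(model_id = seq_len(nrow(calib$scalings))),
               as.data.frame(calib$scalings),
               data.frame(accepted = calib$accepted),
               calib$biomarkers,
               data.frame(rejection_reason = calib$audit$rejection_reason))
  utils::write.csv(out, path, row.names = FALSE)
}
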