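#' In silico trial: single-cell APD arm
#'
#' For every population member and concentration, applies the pore-block
#' profile, paces to steady state at each rate and records APD90 and the
#' within-model change versus the same-model, same-rate control. Models
#' losing capture are kept as rows with `captured = FALSE` and NA APD so
#' they can be counted, and are excluded from population means.
#'
#' The reported APD statistic is APD90 (logged in the column name).
#'
#' @param scalings `n x 8` matrix of accepted scaling vectors.
#' @param profiles Block-profile table (rows of [block_profile_6f()]);
#'   a zero-concentration control row is added if absent.
#' @param rates Pacing rates (Hz).
#' @param params_base Baseline parameters the scalings multiply.
#' @param state0 Shared starting state (settled baseline by default).
#' @param max_beats,tol,dt Passed to [pace_to_steady()].
#' @return data.frame: model_id, concentration_uM, rate_hz, apd90_ms,
#'   d_apd_ms, captured.
#' @export
run_apd_trial <- function(scalings, profiles = block_profile_6f(),
                          rates = 2, params_base = crn_params("AF"),
                          state0 = NULL, max_beats = 40, tol = 1,
                          dt = 0.02) {
  n <- nrow(scalings)
  if (n < 1) stop("population is empty")
  if (!0 %in% profiles$concentration_uM) {
    profiles <- rbind(block_profile(0), profiles)
  }
  profiles <- profiles[order(profiles$concentration_uM), ]
  if (is.null(state0)) {
    state0 <- settle_cell(params_base, duration = 20000, dt = dt)
  }
  rows <- list()
  for (i in seq_len(n)) {
    p_model <- apply_scaling(params_base, scalings[i, ])
    for (ci in seq_len(nrow(profiles))) {
      p <- apply_block(p_model, profiles[ci, ])
      for (r in rates) {
        res <- pace_to_steady(p, 1000 / r, max_beats = max_beats,
                              tol = tol, state0 = state0, dt = dt)
        rows[[length(rows) + 1L]] <- data.frame(
          model_id = i,
          concentration_uM = profiles$concentration_uM[ci],
          rate_hz = r,
          apd90_ms = if (res$captured) res$biomarkers$apd90 else NA_real_,
          captured = res$captured)
      }
    }
  }
  out <- do.call(rbind, rows)
  ctrl <- out[out$concentration_uM == 0,
              c("model_id", "rate_hz", "apd90_ms")]
  names(ctrl)[3] <- "apd90_control"
  out <- merge(out, ctrl, by = c("model_id", "rate_hz"), sort = FALSE)
  out$d_apd_ms <- out$apd90_ms - out$apd90_control
  out$apd90_control <- NULL
  out[order(out$model_id, out$concentration_uM, out$rate_hz), ]
}

#' In silico trial: 1D-cable ERP and propagation arm
#'
#' Measures the effective refractory period per model and concentration on
#' the CV-calibrated cable, the change versus same-model control, and
#' (optionally) 1:1 propagation at each pacing rate. Conduction failures
#' are recorded, never raised.
#'
#' @param scalings `n x 8` matrix of accepted scaling vectors.
#' @param profiles Block-profile table; control row added if absent.
#' @param config Cable configuration with calibrated `diff_coef`.
#' @param protocol An [s1s2_protocol()].
#' @param rates Pacing rates (Hz) for the propagation check; NULL skips it.
#' @param n_stimuli Pulses per propagation check.
#' @param params_base Baseline parameters.
#' @param dt Step (ms).
#' @return List with `erp` (data.frame: model_id, concentration_uM,
#'   erp_ms, d_erp_ms, s1_captured) and `propagation` (data.frame:
#'   model_id, concentration_uM, rate_hz, captures, propagates), the
#'   latter NULL when `rates` is NULL.
#' @export
run_erp_trial <- function(scalings, profiles = block_profile_6f(),
                          config = cable_config(),
                          protocol = s1s2_protocol(), rates = NULL,
                          n_stimuli = 10, params_base = crn_params("AF"),
                          dt = 0.02) {
  n <- nrow(scalings)
  if (n < 1) stop("population is empty")
  if (!0 %in% profiles$concentration_uM) {
    profiles <- rbind(block_profile(0), profiles)
  }
  profiles <- profiles[order(profiles$concentration_uM), ]
  erp_rows <- list(); prop_rows <- list()
  for (i in seq_len(n)) {
    p_model <- apply_scaling(params_base, scalings[i, ])
    for (ci in seq_len(nrow(profiles))) {
      p <- apply_block(p_model, profiles[ci, ])
      erp <- measure_erp(p, config, protocol, dt = dt)
      erp_rows[[length(erp_rows) + 1L]] <- data.frame(
        model_id = i, concentration_uM = profiles$concentration_uM[ci],
        erp_ms = erp$erp_ms, s1_captured = erp$s1_captured)
      if (!is.null(rates)) {
        for (r in rates) {
          pc <- propagation_check(p, config, r, n_stimuli = n_stimuli,
                                  dt = dt)
          prop_rows[[length(prop_rows) + 1L]] <- data.frame(
            model_id = i,
            concentration_uM = profiles$concentration_uM[ci],
            rate_hz = r, captures = pc$captures, propagates = pc$success)
        }
      }
    }
  }
  erp <- do.call(rbind, erp_rows)
  ctrl <- erp[erp$concentration_uM == 0, c("model_id", "erp_ms")]
  names(ctrl)[2] <- "erp_control"
  erp <- merge(erp, ctrl, by = "model_id", sort = FALSE)
  erp$d_erp_ms <- erp$erp_ms - erp$erp_control
  erp$erp_control <- NULL
  erp <- erp[order(erp$model_id, erp$concentration_uM), ]
  prop <- if (length(prop_rows)) do.call(rbind, prop_rows) else NULL
  list(erp = erp, propagation = prop)
}

#' Summarize a trial table
#'
#' Population mean, sample SD (n - 1) and non-missing count of a value
#' column per cell of the grouping grid. Deterministic and invariant to
#' row order; empty cells are reported as NA with count 0.
#'
#' @param result Trial data.frame.
#' @param value Name of the value column (e.g. "apd90_ms", "d_erp_ms").
#' @param by Grouping column names.
#' @return data.frame with the grouping columns plus mean, sd, n.
#' @export
summarize_trial <- function(result, value = "apd90_ms",
                            by = intersect(c("concentration_uM", "rate_hz"),
                                           names(result))) {
  if (nrow(result) == 0) stop("empty trial result")
  groups <- unique(result[by])
  groups <- groups[do.call(order, groups), , drop = FALSE]
  rownames(groups) <- NULL
  stats_ <- lapply(seq_len(nrow(groups)), function(g) {
    sel <- rep(TRUE, nrow(result))
    for (b in by) sel <- sel & result[[b]] == groups[[b]][g]
    x <- result[[value]][sel]
    x <- x[is.finite(x)]
    data.frame(mean = if (length(x)) mean(x) else NA_real_,
               sd = if (length(x) > 1) stats::sd(x) else
                 if (length(x) == 1) 0 else NA_real_,
               n = length(x))
  })
  cbind(groups, do.call(rbind, stats_))
}

#' Fraction of models propagating 1:1, per concentration and rate
#'
#' @param propagation The `propagation` table from [run_erp_trial()].
#' @return data.frame: concentration_uM, rate_hz, n_propagating, n_models,
#'   fraction.
#' @export
propagation_fractions <- function(propagation) {
  groups <- unique(propagation[c("concentration_uM", "rate_hz")])
  groups <- groups[order(groups$concentration_uM, groups$rate_hz), ]
  rownames(groups) <- NULL
  out <- lapply(seq_len(nrow(groups)), function(g) {
    sel <- propagation$concentration_uM == groups$concentration_uM[g] &
      propagation$rate_hz == groups$rate_hz[g]
    n <- sum(sel); k <- sum(propagation$propagates[sel])
    data.frame(n_propagating = k, n_models = n, fraction = k / n)
  })
  cbind(groups, do.call(rbind, out))
}
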