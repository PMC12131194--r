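#' Hill pore-block fraction
#'
#' Fraction of a current blocked at drug concentration `c` under the Hill
#' model `c^h / (c^h + ic50^h)`.
#'
#' @param conc Concentration (uM), >= 0.
#' @param ic50 Half-maximal inhibitory concentration (uM), > 0.
#' @param h Hill coefficient, > 0 (default 1 when only an IC50 is known).
#' @return Blocked fraction in [0, 1).
#' @export
hill_fraction_blocked <- function(conc, ic50, h = 1) {
  if (any(conc < 0)) stop("concentration must be non-negative")
  if (ic50 <= 0) stop("ic50 must be positive")
  if (h <= 0) stop("Hill coefficient must be positive")
  conc^h / (conc^h + ic50^h)
}

#' Ionic current block profiles of compound 6f
#'
#' Packaged per-concentration fractional block of I_Kur (Kv1.5), I_Na
#' (Nav1.5) and I_K2P (TASK-1) derived from the compound's inhibition
#' curves. These printed fractions are the authoritative trial inputs; they
#' are not recomputed from the IC50s.
#'
#' @param concentration Optional concentration (uM) to select a single row
#'   (one of 0, 1, 10, 100). 0 returns the null (no block) profile.
#' @return A data.frame with columns `concentration_uM`, `b_kur`, `b_na`,
#'   `b_k2p` (fractions in [0, 1]); a single-row data.frame when
#'   `concentration` is given.
#' @export
block_profile_6f <- function(concentration = NULL) {
  tab <- data.frame(
    concentration_uM = c(0, 1, 10, 100),
    b_kur = c(0, 0.000, 0.025, 0.50),
    b_na  = c(0, 0.160, 0.300, 0.65),
    b_k2p = c(0, 0.580, 0.750, 0.85))
  if (is.null(concentration)) return(tab)
  row <- tab[tab$concentration_uM == concentration, ]
  if (nrow(row) != 1L) {
    stop("no packaged profile at ", concentration,
         " uM; available: 0, 1, 10, 100")
  }
  row
}

#' Build a block profile from explicit fractions
#'
#' @param concentration_uM Concentration label (uM).
#' @param b_kur,b_na,b_k2p Fractional block of I_Kur, I_Na, I_K2P, each in
#'   [0, 1].
#' @return Single-row data.frame in the same shape as [block_profile_6f()].
#' @export
block_profile <- function(concentration_uM, b_kur = 0, b_na = 0, b_k2p = 0) {
  b <- c(b_kur, b_na, b_k2p)
  if (any(b < 0 | b > 1)) stop("block fractions must lie in [0, 1]")
  data.frame(concentration_uM = concentration_uM,
             b_kur = b_kur, b_na = b_na, b_k2p = b_k2p)
}

#' Apply a pore-block profile to model parameters
#'
#' Scales G_Kur, G_Na and G_K2P by (1 - block fraction); all other
#' parameters are untouched.
#'
#' @param params Parameter vector from [crn_params()].
#' @param profile Single-row block profile (see [block_profile_6f()]).
#' @return Blocked parameter vector.
#' @export
apply_block <- function(params, profile) {
  params <- .check_params(params)
  b <- unlist(profile[1, c("b_kur", "b_na", "b_k2p")])
  if (any(b < 0 | b > 1)) stop("block fractions must lie in [0, 1]")
  params["g_kur"] <- params["g_kur"] * (1 - b[["b_kur"]])
  params["g_na"]  <- params["g_na"] * (1 - b[["b_na"]])
  params["g_k2p"] <- params["g_k2p"] * (1 - b[["b_k2p"]])
  params
}

#' Percent inhibition of a current
#'
#' `100 * (i_control - i_drug) / i_control`. Negative values indicate
#' activation (e.g. TASK-4-type responses) and are returned unclamped.
#'
#' @param i_control Control current (non-zero).
#' @param i_drug Current in the presence of drug.
#' @return Percent inhibition.
#' @export
percent_inhibition <- function(i_control, i_drug) {
  if (any(i_control == 0)) stop("control current must be non-zero")
  100 * (i_control - i_drug) / i_control
}

#' Percent hemolysis from microplate absorbances
#'
#' `100 * (a_d - a_0) / (a_t - a_0)`, with `a_0` the PBS negative control
#' and `a_t` the detergent-lysed positive control.
#'
#' @param a_d Absorbance of the compound-treated well.
#' @param a_0 Negative-control absorbance.
#' @param a_t Positive-control (total lysis) absorbance.
#' @return Percent hemolysis.
#' @export
hemolysis_percent <- function(a_d, a_0, a_t) {
  if (any(a_t == a_0)) stop("no dynamic range: a_t equals a_0")
  100 * (a_d - a_0) / (a_t - a_0)
}

#' Fit the Hill equation to concentration-inhibition data
#'
#' Nonlinear least squares (Levenberg-Marquardt) of
#' `response = c^h / (c^h + ic50^h)` with the IC50 parameterized on the
#' log10 scale. Responses are fraction inhibition in [0, 1]; percent data
#' can be passed with `percent = TRUE`. A fitted `h < 0` (monotone
#' activation rather than inhibition) is flagged, not an error.
#'
#' @param concentrations Concentrations (uM); a zero control row is allowed.
#' @param responses Fraction inhibition (or percent with `percent = TRUE`).
#' @param percent Divide responses by 100 first.
#' @param start Optional list with `ic50` and `h` starting values.
#' @return List with `ic50`, `h`, standard errors, 95% confidence
#'   intervals (`ic50_ci`, `h_ci`), `activation` flag and the `nls` fit.
#' @export
fit_hill <- function(concentrations, responses, percent = FALSE,
                     start = NULL) {
  if (percent) responses <- responses / 100
  keep <- is.finite(concentrations) & is.finite(responses)
  concentrations <- concentrations[keep]; responses <- responses[keep]
  if (length(unique(concentrations[concentrations > 0])) < 4) {
    stop("need >= 4 distinct positive concentrations")
  }
  dat <- data.frame(conc = concentrations, resp = responses)
  if (is.null(start)) {
    pos <- dat[dat$conc > 0, ]
    agg <- stats::aggregate(resp ~ conc, pos, mean)
    ihalf <- which.min(abs(agg$resp - 0.5))
    start <- list(lic = log10(agg$conc[ihalf]), h = 1)
  } else {
    start <- list(lic = log10(start$ic50), h = start$h)
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(
      resp ~ conc^h / (conc^h + (10^lic)^h),
      data = dat, start = start,
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) {
      stop("Hill fit did not converge: ", conditionMessage(e))
    })
  cf <- summary(fit)$coefficients
  lic <- cf["lic", "Estimate"]; se_lic <- cf["lic", "Std. Error"]
  h <- cf["h", "Estimate"]; se_h <- cf["h", "Std. Error"]
  tq <- stats::qt(0.975, stats::df.residual(fit))
  list(ic50 = 10^lic, h = h,
       ic50_se = 10^lic * log(10) * se_lic, h_se = se_h,
       ic50_ci = 10^(lic + c(-1, 1) * tq * se_lic),
       h_ci = h + c(-1, 1) * tq * se_h,
       activation = h < 0,
       fit = fit)
}

#' Fit the Boltzmann equation to a conductance-voltage relation
#'
#' Least-squares fit of `G(V) = 1 / (1 + exp((v_half - V) / k))` to
#' normalized conductances.
#'
#' @param voltages Test potentials (mV), >= 5 points.
#' @param conductances Normalized conductances.
#' @return List with `v_half`, `k`, standard errors and the fit.
#' @export
fit_boltzmann <- function(voltages, conductances) {
  if (length(voltages) < 5) stop("need >= 5 voltage points")
  dat <- data.frame(v = voltages, g = conductances)
  v0 <- dat$v[which.min(abs(dat$g - 0.5))]
  fit <- tryCatch(
    minpack.lm::nlsLM(g ~ 1 / (1 + exp((vh - v) / k)), data = dat,
                      start = list(vh = v0, k = 10)),
    error = function(e) {
      stop("Boltzmann fit did not converge: ", conditionMessage(e))
    })
  cf <- summary(fit)$coefficients
  list(v_half = cf["vh", "Estimate"], k = cf["k", "Estimate"],
       v_half_se = cf["vh", "Std. Error"], k_se = cf["k", "Std. Error"],
       fit = fit)
}

#' Fit a four-parameter logistic (4PL) viability curve
#'
#' `y = bottom + (top - bottom) / (1 + (c / ic50)^slope)`, the standard
#' MTT dose-response model; `y(ic50) = (top + bottom) / 2` by construction.
#'
#' @param concentrations Concentrations (uM), >= 5 distinct values.
#' @param viability Viability (%).
#' @return List with `bottom`, `top`, `ic50`, `slope`, standard errors,
#'   residuals and the fit.
#' @export
fit_4pl <- function(concentrations, viability) {
  if (length(unique(concentrations)) < 5) {
    stop("need >= 5 distinct concentrations")
  }
  dat <- data.frame(conc = concentrations, y = viability)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ bottom + (top - bottom) / (1 + (conc / 10^lic)^slope),
      data = dat,
      start = list(bottom = max(0, min(dat$y)), top = max(dat$y),
                   lic = log10(stats::median(dat$conc)), slope = 1),
      # viability is a percentage: box the asymptotes physiologically
      lower = c(bottom = 0, top = 0, lic = -6, slope = 0.05),
      upper = c(bottom = 120, top = 200, lic = 6, slope = 10),
      control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e) {
      stop("4PL fit did not converge: ", conditionMessage(e))
    })
  cf <- summary(fit)$coefficients
  lic <- cf["lic", "Estimate"]; se_lic <- cf["lic", "Std. Error"]
  tq <- stats::qt(0.975, stats::df.residual(fit))
  list(bottom = cf["bottom", "Estimate"], top = cf["top", "Estimate"],
       ic50 = 10^lic, slope = cf["slope", "Estimate"],
       ic50_se = 10^lic * log(10) * se_lic,
       ic50_ci = 10^(lic + c(-1, 1) * tq * se_lic),
       residuals = stats::residuals(fit),
       fit = fit)
}

#' Read/write dose-response data as CSV
#'
#' Columns: compound, channel, concentration_uM, replicate,
#' response_fraction.
#'
#' @param data Data frame in that shape.
#' @param path File path.
#' @export
write_dose_response_csv <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE)
}

#' @rdname write_dose_response_csv
#' @export
read_dose_response_csv <- function(path) {
  utils::read.csv(path)
}
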