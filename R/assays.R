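# Raw assay readouts -> the concentrations and fractions the estimators
# consume.  All are small, exact conversions; the plateau detector is the
# only one with a heuristic (its slope tolerance follows the trace noise).

#' Complex concentration from absorbance (Beer-Lambert)
#'
#' @param a Absorbance (au, >= 0).
#' @param epsilon Molar absorption coefficient (1/(M cm), > 0); the
#'   Zn(PAR)2 complex has 71500 at 492 nm, pH 7.4.
#' @param path Optical path (cm, > 0), default 1.
#' @return Concentration (molar).
#' @examples
#' absorbance_to_complex_conc(0.0715, 71500)  # 1e-6 M
#' @export
absorbance_to_complex_conc <- function(a, epsilon = 71500, path = 1) {
  check_number(a, "a", min = 0)
  check_number(epsilon, "epsilon", strict_min = 0, len = 1)
  check_number(path, "path", strict_min = 0, len = 1)
  a / (epsilon * path)
}

#' Kinetic trace container
#'
#' @param time_s Strictly increasing times (seconds).
#' @param signal_au Finite signal values.
#' @param reducing_agent Flag: was a reducing agent (e.g. TCEP) present?
#' @return Object of class `kinetic_trace` (a data frame).
#' @export
kinetic_trace <- function(time_s, signal_au, reducing_agent = TRUE) {
  check_number(time_s, "time_s")
  check_number(signal_au, "signal_au")
  if (length(time_s) != length(signal_au))
    zc_stop("time and signal lengths differ")
  if (any(diff(time_s) <= 0)) zc_stop("time must be strictly increasing")
  structure(data.frame(time_s = time_s, signal_au = signal_au),
            reducing_agent = isTRUE(reducing_agent),
            class = c("kinetic_trace", "data.frame"))
}

#' Detect the equilibrium plateau of a kinetic trace
#'
#' Declares a plateau if the linear drift over the final `window` seconds
#' is small against the trace's own noise: the fitted slope times the
#' window must not exceed `max(3 * s, 1e-3 * range)`, where `s` is the
#' median absolute successive difference (a robust noise estimate).  Traces
#' still drifting (e.g. oxidising samples without a reducing agent) return
#' `reached = FALSE`.
#'
#' @param trace A [kinetic_trace()] or data frame with `time_s`, `signal_au`.
#' @param window Final-window length in seconds (default 300).
#' @param slope_tol Optional absolute slope tolerance (au/s); overrides the
#'   noise-derived default.
#' @return List with `plateau` (mean of the final window) and `reached`.
#' @export
detect_plateau <- function(trace, window = 300, slope_tol = NULL) {
  t <- trace$time_s; y <- trace$signal_au
  if (diff(range(t)) < 2 * window)
    zc_stop("trace must span at least twice the plateau window")
  idx <- t >= max(t) - window
  slope <- unname(stats::coef(stats::lm(y[idx] ~ t[idx]))[2])
  if (is.null(slope_tol)) {
    s <- stats::median(abs(diff(y)))
    tol_change <- max(3 * s, 1e-3 * diff(range(y)), 1e-12)
  } else {
    tol_change <- slope_tol * window
  }
  list(plateau = mean(y[idx]),
       reached = is.finite(slope) && abs(slope) * window < tol_change)
}

#' Residual enzyme activity as percent of control
#'
#' @param rate_sample,rate_control Initial rates (au/s); control > 0.
#' @param tol Clipping tolerance above 100 percent before flagging.
#' @return Percent activity, clipped to `[0, 100]`; attribute `over_range`
#'   is TRUE when the raw value exceeded 100 + tol.
#' @examples
#' activity_fraction(0.61, 1)  # 61
#' @export
activity_fraction <- function(rate_sample, rate_control, tol = 5) {
  check_number(rate_sample, "rate_sample", min = 0, len = 1)
  check_number(rate_control, "rate_control", len = 1)
  if (rate_control <= 0) zc_stop("rate_control must be > 0")
  pct <- 100 * rate_sample / rate_control
  structure(min(max(pct, 0), 100), over_range = pct > 100 + tol)
}

#' Saturation fraction from circular-dichroism ellipticity
#'
#' @param theta_obs Observed ellipticity (mdeg).
#' @param theta_apo,theta_holo Metal-free and saturated baselines (mdeg);
#'   must differ.
#' @return Fraction in `[0, 1]`; attribute `out_of_range` flags readings
#'   outside the baselines (noise).
#' @export
cd_saturation_fraction <- function(theta_obs, theta_apo, theta_holo) {
  check_number(theta_obs, "theta_obs", len = 1)
  check_number(theta_apo, "theta_apo", len = 1)
  check_number(theta_holo, "theta_holo", len = 1)
  if (theta_apo == theta_holo) zc_stop("degenerate baselines")
  f <- (theta_obs - theta_apo) / (theta_holo - theta_apo)
  structure(min(max(f, 0), 1), out_of_range = f < 0 || f > 1)
}

#' Metal load per protein from thiol and metal quantitation
#'
#' Converts the thiol (DTNB) and metal (PAR/ICP) concentrations of a
#' cysteine-rich protein into metal equivalents per protein molecule:
#' `zn_per_protein = zinc * n_cys / thiol`.  Human MT2 has 20 cysteines, so
#' a Zn/thiolate ratio of 0.335 corresponds to 6.7 Zn per protein.
#'
#' @param thiol_conc Thiol(ate) concentration (molar, > 0).
#' @param zinc_conc Metal concentration (molar, >= 0).
#' @param n_cys Cysteines per protein (default 20).
#' @return Metal equivalents per protein (dimensionless).
#' @examples
#' zn_per_protein(1, 0.335)  # 6.7
#' @export
zn_per_protein <- function(thiol_conc, zinc_conc, n_cys = 20) {
  check_number(thiol_conc, "thiol_conc", strict_min = 0, len = 1)
  check_number(zinc_conc, "zinc_conc", min = 0, len = 1)
  check_number(n_cys, "n_cys", strict_min = 0, len = 1)
  zinc_conc * n_cys / thiol_conc
}

#' Thiol concentration from a DTNB (Ellman) endpoint absorbance
#'
#' The TNB chromophore released on thiol reaction is quantified at 412 nm.
#' The coefficient is configurable; 14150 1/(M cm) is the standard value
#' for buffered neutral solutions.
#'
#' @param a Absorbance at 412 nm.
#' @param epsilon TNB molar absorption coefficient, default 14150.
#' @param path Path length (cm).
#' @return Thiol concentration (molar).
#' @export
thiol_from_dtnb <- function(a, epsilon = 14150, path = 1) {
  absorbance_to_complex_conc(a, epsilon, path)
}
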