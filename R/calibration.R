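# Reduction of experimental solubility data: linear UV-Vis calibration,
# detection/quantification limits, and composition arithmetic.

#' Fit a linear calibration curve
#'
#' Ordinary least squares of absorbance on concentration,
#' `A = slope * C + intercept`, as used to quantify dissolved API after
#' dilution. The residual standard deviation uses n - 2 degrees of
#' freedom. A constant-absorbance series yields slope 0 and R^2 = 0.
#'
#' @param conc Concentrations (mg/mL), at least 3 points with at least 2
#'   distinct values.
#' @param absorbance Absorbance readings, same length.
#' @return Object of class `calibration_fit`: `slope`, `intercept`,
#'   `r_squared`, `resid_sd`, `n_points`.
#' @seealso [lod_loq()], [simulate_calibration()]
#' @export
#' @examples
#' fit <- fit_calibration(0:3, 2 * (0:3) + 1)
#' fit$slope      # 2
#' fit$r_squared  # 1
fit_calibration <- function(conc, absorbance) {
  if (is.data.frame(conc)) { absorbance <- conc$abs; conc <- conc$conc }
  if (length(conc) != length(absorbance))
    stop("'conc' and 'absorbance' lengths differ")
  if (length(conc) < 3) stop("at least 3 calibration points are required")
  if (length(unique(conc)) < 2)
    stop("calibration requires at least 2 distinct concentrations")
  fit <- stats::lm(absorbance ~ conc)
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((absorbance - mean(absorbance))^2)
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = if (tss > 0) 1 - rss / tss else 0,
                 resid_sd = sqrt(rss / (length(conc) - 2)),
                 n_points = length(conc)),
            class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf("Calibration: A = %.4f * C %s %.4f  (n = %d)\n",
              x$slope, if (x$intercept < 0) "-" else "+",
              abs(x$intercept), x$n_points))
  cat(sprintf("  R^2 = %.4f, residual SD = %.4g\n",
              x$r_squared, x$resid_sd))
  invisible(x)
}

#' Limits of detection and quantification
#'
#' ICH-style limits from a linear calibration:
#' `LOD = 3.3 * sigma / slope` and `LOQ = 10 * sigma / slope`, where
#' `sigma` is the residual standard deviation of the regression. The two
#' limits are therefore always in the fixed ratio `LOQ / LOD = 10 / 3.3`.
#'
#' @param fit A `calibration_fit`, or a positive slope when `resid_sd`
#'   is given directly.
#' @param resid_sd Residual standard deviation (used when `fit` is a
#'   bare slope).
#' @return List with `lod` and `loq` (mg/mL).
#' @export
#' @examples
#' lod_loq(fit_calibration(0:3, 1.5 * (0:3) + rnorm(4, sd = 0.01)))
lod_loq <- function(fit, resid_sd = NULL) {
  if (inherits(fit, "calibration_fit")) {
    slope <- fit$slope; sigma <- fit$resid_sd
  } else {
    if (is.null(resid_sd))
      stop("supply a calibration_fit, or a slope together with 'resid_sd'")
    slope <- fit; sigma <- resid_sd
  }
  if (!is.finite(slope) || slope <= 0)
    stop("LOD/LOQ require a positive calibration slope")
  if (sigma < 0) stop("'resid_sd' must be >= 0")
  list(lod = 3.3 * sigma / slope, loq = 10 * sigma / slope)
}

#' Mole fraction of the API from weighed masses
#'
#' Gravimetric composition: `x_API = n_API / (n_API + sum(n_i))` with
#' `n = mass / Mw`. The result is invariant to rescaling all masses by a
#' common factor. No density is involved, so this is the conversion
#' available when only weighed amounts are known.
#'
#' @param api_mass,api_mw Mass (g) and molar mass (g/mol) of the API.
#' @param masses,mws Masses and molar masses of the other mixture
#'   components (HBA, HBD, water, ...), equal lengths.
#' @return The API mole fraction, a scalar in (0, 1).
#' @export
#' @examples
#' # equal moles of API and one solvent
#' mole_fraction_from_masses(1, 100, 2, 200)  # 0.5
mole_fraction_from_masses <- function(api_mass, api_mw, masses, mws) {
  if (length(masses) != length(mws))
    stop("'masses' and 'mws' lengths differ")
  vals <- c(api_mass, api_mw, masses, mws)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("masses and molar masses must be positive")
  n_api <- api_mass / api_mw
  n_api / (n_api + sum(masses / mws))
}

#' Percent decrease from a peak value
#'
#' `100 * (1 - value / peak)`, the summary used to quantify the
#' hydration-induced decline of solubility from its low-water peak.
#'
#' @param peak Reference (peak) value, positive.
#' @param value Current value.
#' @return Percent decrease (may be negative if `value > peak`).
#' @export
#' @examples
#' percent_decrease(71.87, 16.24)  # ~77.4
percent_decrease <- function(peak, value) {
  if (!is.finite(peak) || peak <= 0) stop("'peak' must be positive")
  100 * (1 - value / peak)
}
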