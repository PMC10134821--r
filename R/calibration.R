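#' Fit a linear calibration curve
#'
#' Ordinary least squares of absorbance against standard concentration,
#' `OD = slope * C + intercept`. Replicate standards are fitted jointly
#' (every point enters the regression). For a dye measured at its
#' isosbestic point, or an endpoint enzymatic assay, this line converts OD
#' into concentration.
#'
#' @param standards A data frame with columns `concentration` (mmol/L, or
#'   any concentration unit carried through consistently) and `od`.
#' @return An object of class `calibration_fit` with components `slope`
#'   (OD per concentration unit), `intercept` (OD), `r_squared`, and the
#'   underlying `lm` fit.
#' @seealso [apply_calibration()]
#' @export
fit_calibration <- function(standards) {
  standards <- as.data.frame(standards)
  stopifnot(all(c("concentration", "od") %in% names(standards)))
  if (length(unique(standards$concentration)) < 2) {
    stop("need at least two distinct standard concentrations")
  }
  fit <- stats::lm(od ~ concentration, data = standards)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((standards$od - mean(standards$od))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  structure(
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r_squared = r2, lm = fit, standards = standards),
    class = "calibration_fit"
  )
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat("Linear calibration: OD = slope * C + intercept\n")
  cat(sprintf("  slope     %.6g OD per unit concentration\n", x$slope))
  cat(sprintf("  intercept %.6g OD\n", x$intercept))
  cat(sprintf("  r-squared %.6f  (n = %d standards)\n",
              x$r_squared, nrow(x$standards)))
  invisible(x)
}

#' @export
coef.calibration_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
predict.calibration_fit <- function(object, concentration, ...) {
  object$intercept + object$slope * concentration
}

#' Convert an OD series to concentration via a calibration line
#'
#' Inverts the calibration line, `C = (OD - intercept) / slope`, and floors
#' the result at zero: noise near the blank can push the inverted values
#' slightly negative, and downstream diffusion fitting assumes non-negative
#' concentrations.
#'
#' @param series A [kinetic_series()] in OD units.
#' @param curve A [fit_calibration()] result, or any list with positive
#'   `slope` and `intercept` elements.
#' @return A `kinetic_series` in mmol/L (the concentration unit of the
#'   standards used to build `curve`).
#' @export
apply_calibration <- function(series, curve) {
  stopifnot(inherits(series, "kinetic_series"))
  if (series$unit != "OD") {
    stop("apply_calibration expects an OD series")
  }
  if (!is.numeric(curve$slope) || curve$slope <= 0) {
    stop("calibration slope must be positive")
  }
  conc <- (series$values - curve$intercept) / curve$slope
  conc[conc < 0] <- 0
  kinetic_series(series$times, conc, wells = series$wells, unit = "mmol/L",
                 wavelength_nm = series$wavelength_nm)
}

#' Dilution fraction to reach a target OD
#'
#' Fraction of culture in the dilution needed to bring a washed culture to
#' a target OD600, on the blank-corrected scale:
#' `(target - blank) / (culture - blank)`.
#'
#' @param target_od Desired OD600 of the dilution.
#' @param culture_od Measured OD600 of the culture.
#' @param blank_od Measured OD600 of the medium blank.
#' @return Fraction in `[0, 1]`.
#' @export
dilution_fraction <- function(target_od, culture_od, blank_od) {
  if (culture_od <= blank_od) {
    stop("culture OD must exceed blank OD (no culture signal)")
  }
  if (target_od < blank_od) {
    stop("target OD below blank OD")
  }
  frac <- (target_od - blank_od) / (culture_od - blank_od)
  if (frac > 1) {
    stop("culture is more dilute than the target (fraction > 1)")
  }
  frac
}

#' Amino-acid supplementation concentration for a target cell yield
#'
#' Molar concentration of an amino acid that would be fully converted into
#' a given number of cells: `aa_per_cell * target_cells / (N_A * volume)`,
#' with Avogadro's number `N_A = 6.022e23`. Used to dose minimal medium so
#' an auxotroph's theoretical yield is a chosen cell count.
#'
#' @param aa_per_cell Amino-acid molecules incorporated per cell.
#' @param target_cells Target cell yield.
#' @param volume Culture volume in litres.
#' @return Concentration in mol/L.
#' @export
supplement_concentration <- function(aa_per_cell, target_cells, volume) {
  stopifnot(aa_per_cell > 0, target_cells > 0, volume > 0)
  aa_per_cell * target_cells / (6.022e23 * volume)
}

#' Convert a molar concentration to percent weight/volume
#'
#' @param conc_mol_l Concentration in mol/L.
#' @param mw Molecular weight in g/mol.
#' @return Percent w/v (g per 100 mL).
#' @export
percent_wv <- function(conc_mol_l, mw) {
  conc_mol_l * mw / 10
}
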