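#' Construct a kinetic time series
#'
#' A `kinetic_series` holds a plate-reader kinetic read: a strictly
#' increasing time grid (hours) and one trace per well, either raw
#' absorbance (`unit = "OD"`) or calibrated concentration
#' (`unit = "mmol/L"`).
#'
#' @param times Numeric vector of time points in hours, strictly increasing.
#' @param values Numeric matrix, `length(times)` rows, one column per well.
#' @param wells Character vector of well identifiers (e.g. `"A1"`). Defaults
#'   to the column names of `values`.
#' @param unit Measurement unit, `"OD"` or `"mmol/L"`.
#' @param wavelength_nm Optional measurement wavelength in nm.
#'
#' @return An object of class `kinetic_series`: a list with elements
#'   `times`, `wells`, `values`, `unit` and `wavelength_nm`.
#' @export
kinetic_series <- function(times, values, wells = colnames(values),
                           unit = c("OD", "mmol/L"), wavelength_nm = NULL) {
  unit <- match.arg(unit)
  times <- as.numeric(times)
  values <- as.matrix(values)
  if (is.null(wells)) {
    stop("'wells' must be supplied when 'values' has no column names")
  }
  wells <- as.character(wells)
  if (anyNA(times) || anyNA(values)) {
    stop("kinetic series must not contain missing values")
  }
  if (length(times) != nrow(values)) {
    stop("length(times) must equal nrow(values)")
  }
  if (length(wells) != ncol(values)) {
    stop("length(wells) must equal ncol(values)")
  }
  if (length(times) > 1 && any(diff(times) <= 0)) {
    stop("times must be strictly increasing")
  }
  if (anyDuplicated(wells)) {
    stop("well identifiers must be unique")
  }
  dimnames(values) <- list(NULL, wells)
  structure(
    list(times = times, wells = wells, values = values, unit = unit,
         wavelength_nm = wavelength_nm),
    class = "kinetic_series"
  )
}

#' @export
print.kinetic_series <- function(x, ...) {
  cat(sprintf("Kinetic series: %d timepoints x %d wells [%s]\n",
              length(x$times), length(x$wells), x$unit))
  cat(sprintf("  time span: %.3g to %.3g h (median step %.3g h)\n",
              min(x$times), max(x$times),
              if (length(x$times) > 1) stats::median(diff(x$times)) else NA))
  cat("  wells:", paste(utils::head(x$wells, 8L), collapse = ", "),
      if (length(x$wells) > 8L) "..." else "", "\n")
  invisible(x)
}

#' @export
as.data.frame.kinetic_series <- function(x, ...) {
  data.frame(time = x$times, x$values, check.names = FALSE)
}

#' @export
plot.kinetic_series <- function(x, wells = x$wells, ...) {
  ylab <- if (x$unit == "OD") "absorbance (OD)" else "concentration (mmol/L)"
  graphics::matplot(x$times, x$values[, wells, drop = FALSE], type = "l",
                    lty = 1, xlab = "time (h)", ylab = ylab, ...)
  graphics::legend("topright", legend = wells, lty = 1, bty = "n",
                   col = seq_along(wells))
  invisible(x)
}

#' Extract single-well traces
#'
#' @param series A [kinetic_series()].
#' @param wells Wells to keep.
#' @return A `kinetic_series` restricted to `wells`.
#' @export
subset_wells <- function(series, wells) {
  stopifnot(inherits(series, "kinetic_series"))
  missing_w <- setdiff(wells, series$wells)
  if (length(missing_w) > 0) {
    stop("unknown wells: ", paste(missing_w, collapse = ", "))
  }
  kinetic_series(series$times, series$values[, wells, drop = FALSE],
                 wells = wells, unit = series$unit,
                 wavelength_nm = series$wavelength_nm)
}
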