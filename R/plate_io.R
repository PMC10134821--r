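#' Read a plate-reader kinetic table
#'
#' Reads a wide CSV export: first column is time, remaining columns are one
#' well each (header row gives the well IDs). Times are canonicalized to
#' hours internally, whatever the export's unit, because every rate in the
#' models carries per-hour units.
#'
#' @param path Path to the CSV file.
#' @param unit Measurement unit of the values, `"OD"` or `"mmol/L"`.
#' @param time_unit Unit of the time column: `"hours"`, `"minutes"` or
#'   `"seconds"`.
#' @param wavelength_nm Optional wavelength annotation.
#'
#' @return A [kinetic_series()].
#' @export
load_kinetic_table <- function(path, unit = c("OD", "mmol/L"),
                               time_unit = c("hours", "minutes", "seconds"),
                               wavelength_nm = NULL) {
  unit <- match.arg(unit)
  time_unit <- match.arg(time_unit)
  tab <- utils::read.csv(path, check.names = FALSE)
  if (ncol(tab) < 2) {
    stop("kinetic table needs a time column plus at least one well column")
  }
  na_idx <- which(is.na(as.matrix(tab)), arr.ind = TRUE)
  if (nrow(na_idx) > 0) {
    stop(sprintf("missing value at row %d, column '%s' of %s",
                 na_idx[1, 1], colnames(tab)[na_idx[1, 2]], path))
  }
  times <- as.numeric(tab[[1]])
  if (length(times) > 1 && any(diff(times) <= 0)) {
    stop("time column is not strictly increasing in ", path)
  }
  times <- switch(time_unit,
                  hours = times,
                  minutes = times / 60,
                  seconds = times / 3600)
  values <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(values) <- "double"
  kinetic_series(times, values, wells = colnames(tab)[-1], unit = unit,
                 wavelength_nm = wavelength_nm)
}

#' Write a kinetic table
#'
#' Inverse of [load_kinetic_table()]: writes the wide CSV layout (first
#' column `time`, in hours).
#'
#' @param series A [kinetic_series()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_kinetic_table <- function(series, path) {
  stopifnot(inherits(series, "kinetic_series"))
  utils::write.csv(as.data.frame(series), path, row.names = FALSE)
  invisible(path)
}

#' Subtract blank wells from a kinetic series
#'
#' Subtracts the per-timepoint mean of the blank wells from every other
#' trace, putting the measurements on a ratio scale. Using the blank's own
#' time course (rather than a scalar) absorbs reader drift; it reduces to a
#' scalar offset when the blanks are constant. Blank wells are dropped from
#' the result.
#'
#' @param series A [kinetic_series()].
#' @param blanks Character vector of blank well IDs, a non-empty subset of
#'   `series$wells`.
#' @return A `kinetic_series` of the remaining wells, blank-corrected.
#' @export
blank_subtract <- function(series, blanks) {
  stopifnot(inherits(series, "kinetic_series"))
  if (length(blanks) == 0) {
    stop("at least one blank well is required")
  }
  missing_b <- setdiff(blanks, series$wells)
  if (length(missing_b) > 0) {
    stop("blank wells not in series: ", paste(missing_b, collapse = ", "))
  }
  keep <- setdiff(series$wells, blanks)
  if (length(keep) == 0) {
    stop("no non-blank wells left after dropping blanks")
  }
  blank_mean <- rowMeans(series$values[, blanks, drop = FALSE])
  corrected <- series$values[, keep, drop = FALSE] - blank_mean
  kinetic_series(series$times, corrected, wells = keep, unit = series$unit,
                 wavelength_nm = series$wavelength_nm)
}

#' Plate map for paired coculture wells
#'
#' Encodes the hardware layout: which left/right wells face each other
#' across a membrane, what each well contains, and which wells are blanks.
#' The pairing is a property of the device and is always stated explicitly,
#' never inferred from plate geometry.
#'
#' @param pairs A data frame with columns `left`, `right`, `pore_size`
#'   (pore-size label: `"none"`, `"0.03"`, `"0.1"`, `"0.2"` or `"0.4"` um).
#' @param contents Named character vector or list describing per-well
#'   contents (strain / dye / medium).
#' @param blanks Character vector of blank well IDs.
#' @return An object of class `plate_map`.
#' @export
plate_map <- function(pairs, contents = list(), blanks = character()) {
  pairs <- as.data.frame(pairs)
  stopifnot(all(c("left", "right", "pore_size") %in% names(pairs)))
  pairs$pore_size <- as.character(pairs$pore_size)
  bad_pore <- setdiff(unique(pairs$pore_size),
                      c("none", "0.03", "0.1", "0.2", "0.4"))
  if (length(bad_pore) > 0) {
    stop("unknown pore-size labels: ", paste(bad_pore, collapse = ", "))
  }
  paired_wells <- c(pairs$left, pairs$right)
  if (anyDuplicated(paired_wells)) {
    stop("each well may appear in at most one pair")
  }
  structure(list(pairs = pairs, contents = as.list(contents),
                 blanks = as.character(blanks)),
            class = "plate_map")
}

#' @export
print.plate_map <- function(x, ...) {
  cat(sprintf("Plate map: %d well pairs, %d blanks\n",
              nrow(x$pairs), length(x$blanks)))
  print(x$pairs)
  invisible(x)
}

#' Read / write plate maps as YAML
#'
#' @param path YAML file path.
#' @return For `load_plate_map`, a [plate_map()]; for `write_plate_map`,
#'   `path` invisibly.
#' @export
load_plate_map <- function(path) {
  y <- yaml::read_yaml(path)
  pairs <- do.call(rbind, lapply(y$pairs, function(p) {
    data.frame(left = p$left, right = p$right,
               pore_size = as.character(p$pore_size))
  }))
  plate_map(pairs, contents = y$contents,
            blanks = as.character(unlist(y$blanks)))
}

#' @rdname load_plate_map
#' @param map A [plate_map()].
#' @export
write_plate_map <- function(map, path) {
  stopifnot(inherits(map, "plate_map"))
  y <- list(
    pairs = lapply(seq_len(nrow(map$pairs)), function(i) {
      list(left = map$pairs$left[i], right = map$pairs$right[i],
           pore_size = map$pairs$pore_size[i])
    }),
    contents = map$contents,
    blanks = as.list(map$blanks)
  )
  yaml::write_yaml(y, path)
  invisible(path)
}
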