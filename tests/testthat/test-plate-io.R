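test_that("kinetic tables load with time canonicalized to hours", {
  path <- write_tiny_table()
  ks <- load_kinetic_table(path, unit = "OD")
  expect_s3_class(ks, "kinetic_series")
  expect_equal(ks$times, c(0, 0.25, 0.5))
  expect_equal(ks$wells, c("A1", "A2"))
  expect_equal(dim(ks$values), c(3L, 2L))

  # minutes flag: 0/15/30 min become 0/0.25/0.5 h
  path_min <- write_tiny_table(times = c(0, 15, 30))
  ks_min <- load_kinetic_table(path_min, unit = "OD", time_unit = "minutes")
  expect_equal(ks_min$times, c(0, 0.25, 0.5))
})

test_that("malformed kinetic tables are rejected with informative errors", {
  path <- write_tiny_table(times = c(0, 0.5, 0.25))
  expect_error(load_kinetic_table(path, "OD"), "not strictly increasing")

  df <- data.frame(time = c(0, 0.25), A1 = c(0.1, NA))
  path_na <- tempfile(fileext = ".csv")
  utils::write.csv(df, path_na, row.names = FALSE)
  expect_error(load_kinetic_table(path_na, "OD"), "row 2.*A1")
})

test_that("kinetic tables round-trip through save/load", {
  gen <- gen_dye_experiment(synthetic_truth(seed = 3))
  path <- tempfile(fileext = ".csv")
  write_kinetic_table(gen$table, path)
  back <- load_kinetic_table(path, unit = "OD")
  expect_equal(back$times, gen$table$times)
  expect_equal(back$wells, gen$table$wells)
  expect_equal(back$values, gen$table$values, tolerance = 1e-12)
})

test_that("blank subtraction removes the per-timepoint blank mean", {
  times <- c(0, 1, 2)
  vals <- cbind(S1 = c(0.50, 0.52, 0.54),  # blank + 0.4 approx
                B1 = c(0.09, 0.10, 0.11),
                B2 = c(0.11, 0.12, 0.13))
  ks <- kinetic_series(times, vals, unit = "OD")
  out <- blank_subtract(ks, c("B1", "B2"))
  expect_equal(out$wells, "S1")
  expect_equal(unname(out$values[, "S1"]), c(0.40, 0.41, 0.42))

  # well identical to the blank mean -> all-zero trace
  ks2 <- kinetic_series(times, cbind(S = c(0.1, 0.2, 0.3),
                                     B = c(0.1, 0.2, 0.3)), unit = "OD")
  expect_equal(unname(blank_subtract(ks2, "B")$values[, 1]), c(0, 0, 0))

  # constant offset over the blank -> constant trace
  ks3 <- kinetic_series(times, cbind(S = c(0.4, 0.5, 0.6),
                                     B = c(0.1, 0.2, 0.3)), unit = "OD")
  expect_equal(unname(blank_subtract(ks3, "B")$values[, 1]), rep(0.3, 3))

  # subtracting an all-zero blank is the identity
  ks4 <- kinetic_series(times, cbind(S = c(0.4, 0.5, 0.6), Z = c(0, 0, 0)),
                        unit = "OD")
  expect_equal(unname(blank_subtract(ks4, "Z")$values[, 1]), c(0.4, 0.5, 0.6))

  expect_error(blank_subtract(ks, character()), "at least one blank")
  expect_error(blank_subtract(ks, "Z9"), "not in series")
})

test_that("calibration fits recover exact lines and match closed-form OLS", {
  std <- exact_standards(slope = 0.001 * 1000, intercept = 0.05)
  cal <- fit_calibration(std)
  expect_equal(cal$slope, 1, tolerance = 1e-12)
  expect_equal(cal$intercept, 0.05, tolerance = 1e-12)
  expect_equal(cal$r_squared, 1, tolerance = 1e-12)

  # standard lysine assay ladder is a valid input
  ladder <- data.frame(concentration = rep(c(100, 50, 25, 12.5, 6.25, 0), 2) / 1000)
  ladder$od <- 0.05 + 1 * ladder$concentration
  expect_silent(fit_calibration(ladder))

  # closed-form least-squares slope on noisy points
  set.seed(7)
  x <- c(0.1, 0.2, 0.4)
  y <- 0.05 + 0.9 * x + rnorm(3, 0, 0.01)
  cal2 <- fit_calibration(data.frame(concentration = x, od = y))
  slope_oracle <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  intercept_oracle <- mean(y) - slope_oracle * mean(x)
  expect_equal(cal2$slope, slope_oracle, tolerance = 1e-12)
  expect_equal(cal2$intercept, intercept_oracle, tolerance = 1e-12)

  expect_error(fit_calibration(data.frame(concentration = c(1, 1),
                                          od = c(0.1, 0.2))),
               "distinct")
})

test_that("applying a calibration inverts the line, floored at zero", {
  cal <- list(slope = 1, intercept = 0.05)  # 0.001 OD/uM on the mmol/L scale
  times <- c(0, 1)
  od <- kinetic_series(times, cbind(W = c(0.45, 0.05)), unit = "OD")
  conc <- apply_calibration(od, cal)
  expect_equal(conc$unit, "mmol/L")
  expect_equal(unname(conc$values[, 1]), c(0.4, 0))  # 400 uM, then 0

  # OD below the intercept floors at zero, never negative
  od_low <- kinetic_series(times, cbind(W = c(0.04, 0.01)), unit = "OD")
  expect_true(all(apply_calibration(od_low, cal)$values >= 0))

  expect_error(apply_calibration(od, list(slope = -1, intercept = 0)),
               "slope")
  expect_error(apply_calibration(conc, cal), "OD series")
})

test_that("calibration round-trips: forward map then inversion recovers C", {
  for (slope in c(1e-4, 1e-2, 1)) {
    conc_true <- c(0, 0.00625, 0.0125, 0.025, 0.05, 0.1)
    cal <- list(slope = slope, intercept = 0.05)
    od <- kinetic_series(seq_along(conc_true),
                         matrix(0.05 + slope * conc_true, ncol = 1,
                                dimnames = list(NULL, "W")),
                         unit = "OD")
    back <- apply_calibration(od, cal)
    expect_equal(unname(back$values[, 1]), conc_true, tolerance = 1e-12)
  }
})

test_that("dilution fraction follows the blank-corrected ratio", {
  expect_equal(dilution_fraction(0.1, 2.05, 0.05), 0.025)
  expect_equal(dilution_fraction(0.5, 0.5, 0.05), 1.0)
  expect_equal(dilution_fraction(0.1, 1.1, 0.1), 0.0)
  # invariant under a common offset to all three ODs
  expect_equal(dilution_fraction(0.1 + 0.3, 2.05 + 0.3, 0.05 + 0.3), 0.025)
  expect_error(dilution_fraction(0.1, 0.04, 0.05), "culture OD")
  expect_error(dilution_fraction(0.2, 0.15, 0.05), "fraction > 1")
})

test_that("supplementation doses reproduce the printed molarities", {
  # lysine: 1.1e8 aa/cell for a 1e9-cell yield in 250 uL
  lys <- supplement_concentration(1.1e8, 1e9, 2.5e-4)
  expect_equal(lys, 7.3065e-4, tolerance = 1e-4)
  expect_equal(1000 * lys, 0.731, tolerance = 1e-3)  # mmol/L as dosed

  # isoleucine: 7.5e7 aa/cell
  ile <- supplement_concentration(7.5e7, 1e9, 2.5e-4)
  expect_equal(ile, 4.98e-4, tolerance = 1e-3)
  expect_equal(percent_wv(ile, 131.17), 0.0065, tolerance = 1e-2)

  # doubling the volume halves the concentration
  expect_equal(supplement_concentration(1.1e8, 1e9, 5e-4), lys / 2)
  expect_error(supplement_concentration(0, 1e9, 2.5e-4))
})

test_that("plate maps validate pairing and round-trip through YAML", {
  pm <- plate_map(data.frame(left = c("A1", "B1"), right = c("A2", "B2"),
                             pore_size = c("0.1", "none")),
                  contents = list(A1 = "dye", A2 = "water"),
                  blanks = "H1")
  path <- tempfile(fileext = ".yaml")
  write_plate_map(pm, path)
  back <- load_plate_map(path)
  expect_equal(back$pairs, pm$pairs)
  expect_equal(back$blanks, pm$blanks)

  expect_error(plate_map(data.frame(left = c("A1", "A1"),
                                    right = c("A2", "A3"),
                                    pore_size = "0.1")),
               "at most one pair")
  expect_error(plate_map(data.frame(left = "A1", right = "A2",
                                    pore_size = "0.5")),
               "pore-size")
})
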