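#' Ground-truth record for synthetic dataset generation
#'
#' Bundles every parameter a generator needs, plus the RNG seed, so each
#' generated dataset is exactly reproducible and every downstream recovery
#' test can compare against known truth.
#'
#' Defaults emulate the standard experiments: 400 uM (0.4 mmol/L) dye or
#' amino acid loaded into 250-uL left wells against water/buffer on the
#' right; dye kinetics read for 72 h at 15-min intervals; growth read for
#' 96 h at 15-min intervals; amino acids destructively sampled at 1.5, 3,
#' 6, 12 and 24 h. Per-pore-size diffusion rates rise monotonically with
#' pore size (anchored at the measured 3.88e-5 L/h for the 0.1-um
#' membrane). The OD/concentration map is the linear calibration
#' `OD = slope * C + intercept` and measurement noise is additive i.i.d.
#' Gaussian on OD, floored at zero.
#'
#' @param seed Integer RNG seed recorded with the dataset.
#' @param d_by_pore Named numeric vector of diffusion rates (L/h) per
#'   pore-size label.
#' @param volume Well volume, L.
#' @param load_mM Loaded concentration in the left well, mmol/L.
#' @param cal_slope Calibration slope, OD per mmol/L (0.001 OD/uM).
#' @param cal_intercept Calibration intercept, OD.
#' @param noise_sd Gaussian noise standard deviation on OD.
#' @param loss_rate First-order input-well loss rate (1/h) emulating dye
#'   sequestration in the membrane; 0 disables it.
#' @param n_replicates Replicate pairs per condition.
#' @param od_to_gdw_per_l Biomass conversion for growth curves, gDW/L per
#'   OD600 unit.
#' @param blank_od Medium blank OD offset added to growth curves.
#' @param strains Strain parameters for growth-curve generation.
#' @param d Membrane rate used for growth scenarios, L/h.
#' @return An object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(seed = 1,
                            d_by_pore = c(none = 0, "0.03" = 1e-5,
                                          "0.1" = 3.88e-5, "0.2" = 1e-4,
                                          "0.4" = 2.5e-4),
                            volume = 2.5e-4, load_mM = 0.4,
                            cal_slope = 1, cal_intercept = 0.05,
                            noise_sd = 0.005, loss_rate = 0,
                            n_replicates = 3,
                            od_to_gdw_per_l = 0.5, blank_od = 0.05,
                            strains = default_strains(), d = 3.88e-5) {
  stopifnot(all(d_by_pore >= 0), noise_sd >= 0, loss_rate >= 0,
            cal_slope > 0, volume > 0, load_mM >= 0)
  structure(list(seed = as.integer(seed), d_by_pore = d_by_pore,
                 volume = volume, load_mM = load_mM,
                 cal_slope = cal_slope, cal_intercept = cal_intercept,
                 noise_sd = noise_sd, loss_rate = loss_rate,
                 n_replicates = n_replicates,
                 od_to_gdw_per_l = od_to_gdw_per_l, blank_od = blank_od,
                 strains = strains, d = d),
            class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("Synthetic ground truth (seed", x$seed, ")\n")
  cat("  d by pore size (L/h):",
      paste(sprintf("%s=%.3g", names(x$d_by_pore), x$d_by_pore),
            collapse = ", "), "\n")
  cat(sprintf("  calibration OD = %.4g * C + %.4g; noise sd %.4g OD; loss %.3g 1/h\n",
              x$cal_slope, x$cal_intercept, x$noise_sd, x$loss_rate))
  invisible(x)
}

.dye_schedule <- function() seq(0, 72, by = 0.25)      # 289 timepoints
.growth_schedule <- function() seq(0, 96, by = 0.25)   # 385 timepoints
.aa_schedule <- function() c(1.5, 3, 6, 12, 24)

#' Generate a synthetic dye-diffusion experiment
#'
#' One 72-h kinetic OD table: for each pore size, `n_replicates` well
#' pairs loaded with dye on the left and water on the right. Traces follow
#' the two-well diffusion model (analytic when `loss_rate = 0`, numeric
#' otherwise), mapped to OD through the calibration line, with additive
#' Gaussian noise. Blank (water-only) wells are included.
#'
#' @param truth A [synthetic_truth()].
#' @return List with `table` (a [kinetic_series()] in OD), `map` (a
#'   [plate_map()]) and `truth`.
#' @export
gen_dye_experiment <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  set.seed(truth$seed)
  times <- .dye_schedule()
  pores <- names(truth$d_by_pore)
  rows <- LETTERS[seq_along(pores)]
  wells <- character(0)
  traces <- list()
  pairs <- NULL
  for (i in seq_along(pores)) {
    sys <- diffusion_system(truth$d_by_pore[[i]], truth$volume, truth$volume,
                            truth$load_mM, 0)
    sol <- if (truth$loss_rate > 0) {
      simulate_diffusion(sys, times, loss_rate = truth$loss_rate)
    } else {
      analytic_two_well(sys, times)
    }
    for (r in seq_len(truth$n_replicates)) {
      wl <- sprintf("%s%d", rows[i], 2 * r - 1)
      wr <- sprintf("%s%d", rows[i], 2 * r)
      traces[[wl]] <- sol$c_left
      traces[[wr]] <- sol$c_right
      wells <- c(wells, wl, wr)
      pairs <- rbind(pairs, data.frame(left = wl, right = wr,
                                       pore_size = pores[i]))
    }
  }
  blank_wells <- sprintf("H%d", seq_len(truth$n_replicates))
  for (b in blank_wells) traces[[b]] <- rep(0, length(times))
  conc <- do.call(cbind, traces)
  od <- truth$cal_intercept + truth$cal_slope * conc
  if (truth$noise_sd > 0) {
    od <- od + stats::rnorm(length(od), 0, truth$noise_sd)
  }
  od[od < 0] <- 0
  series <- kinetic_series(times, od, wells = c(wells, blank_wells),
                           unit = "OD")
  contents <- c(stats::setNames(as.list(rep("dye", length(wells))), wells),
                stats::setNames(as.list(rep("water", length(blank_wells))),
                                blank_wells))
  map <- plate_map(pairs, contents = contents, blanks = blank_wells)
  list(table = series, map = map, truth = truth)
}

#' Generate a synthetic destructive amino-acid sampling experiment
#'
#' Emulates the enzymatic-assay measurement of amino-acid diffusion across
#' the 0.1-um membrane: both wells of `n_replicates` independent pairs are
#' destructively sampled at 1.5, 3, 6, 12 and 24 h (each replicate is a
#' separate pair of wells, not a repeated measure), concentrations follow
#' the analytic two-well model plus assay noise, and the matching standard
#' ladders (lysine 100..0 uM, isoleucine 1000..0 uM) are emitted on the
#' same linear calibration.
#'
#' @param truth A [synthetic_truth()]. `d` (not `d_by_pore`) is the rate
#'   used, one amino acid at a time.
#' @param amino_acid `"lysine"` or `"isoleucine"`.
#' @return List with `samples` (data frame: `time_h`, `side`, `replicate`,
#'   `concentration_mM`), `standards` (data frame: `concentration`, `od`),
#'   and `truth`.
#' @export
gen_amino_acid_sampling <- function(truth,
                                    amino_acid = c("lysine", "isoleucine")) {
  stopifnot(inherits(truth, "synthetic_truth"))
  amino_acid <- match.arg(amino_acid)
  set.seed(truth$seed + 1L)
  times <- .aa_schedule()
  sys <- diffusion_system(truth$d, truth$volume, truth$volume,
                          truth$load_mM, 0)
  sol <- analytic_two_well(sys, times)
  grid <- expand.grid(replicate = seq_len(truth$n_replicates),
                      side = c("left", "right"), time_h = times,
                      stringsAsFactors = FALSE)
  truth_conc <- ifelse(grid$side == "left",
                       sol$c_left[match(grid$time_h, sol$time)],
                       sol$c_right[match(grid$time_h, sol$time)])
  noise_mM <- truth$noise_sd / truth$cal_slope
  conc <- truth_conc + if (truth$noise_sd > 0) {
    stats::rnorm(nrow(grid), 0, noise_mM)
  } else 0
  conc[conc < 0] <- 0
  samples <- data.frame(time_h = grid$time_h, side = grid$side,
                        replicate = grid$replicate,
                        concentration_mM = conc)
  ladder_uM <- if (amino_acid == "lysine") {
    c(100, 50, 25, 12.5, 6.25, 0)
  } else {
    c(1000, 500, 250, 125, 62.5, 31.25, 15.63, 0)
  }
  ladder_mM <- ladder_uM / 1000
  standards <- data.frame(
    concentration = ladder_mM,
    od = truth$cal_intercept + truth$cal_slope * ladder_mM)
  list(samples = samples, standards = standards, truth = truth,
       amino_acid = amino_acid)
}

#' Generate synthetic growth-curve kinetic tables
#'
#' Runs the coculture model for each requested scenario over the 96-h
#' plate-reader schedule and converts biomass to OD600 via the configured
#' gDW/L-per-OD factor, adding the blank offset and Gaussian noise. Each
#' strain in each compartment gets its own column (synthetic data may
#' resolve strains within a shared well, which real OD cannot), plus blank
#' wells.
#'
#' @param truth A [synthetic_truth()].
#' @param scenarios Character vector of [build_experiment()] scenarios.
#' @param t_end Horizon in hours (default 96).
#' @param ... Passed to [build_experiment()] (e.g. `aa_seed_mM`).
#' @return List with one element per scenario, each holding `table` (a
#'   [kinetic_series()] in OD; columns `<scenario>.<comp>.<strain>` and
#'   blanks), `trajectory`, and shared `truth`.
#' @export
gen_growth_experiment <- function(truth,
                                  scenarios = c("same_well_positive",
                                                "separated_coculture"),
                                  t_end = 96, ...) {
  stopifnot(inherits(truth, "synthetic_truth"))
  set.seed(truth$seed + 2L)
  times <- seq(0, t_end, by = 0.25)
  out <- lapply(scenarios, function(sc) {
    sys <- build_experiment(sc, strains = truth$strains, d = truth$d,
                            volume = truth$volume,
                            od_to_gdw_per_l = truth$od_to_gdw_per_l, ...)
    traj <- simulate_coculture(sys, t_end = t_end, times = times)
    cols <- list()
    for (w in seq_along(sys$compartments)) {
      for (s in c("dLys", "dIle")) {
        if (sys$compartments[[w]]$biomass[s] > 0) {
          b <- traj$states[, sprintf("B%d.%s", w, s)]
          od <- truth$blank_od +
            b / sys$compartments[[w]]$volume / truth$od_to_gdw_per_l
          cols[[sprintf("%s.%d.%s", sc, w, s)]] <- od
        }
      }
    }
    for (b in 1:2) {
      cols[[sprintf("%s.blank%d", sc, b)]] <- rep(truth$blank_od,
                                                  length(times))
    }
    od <- do.call(cbind, cols)
    if (truth$noise_sd > 0) {
      od <- od + stats::rnorm(length(od), 0, truth$noise_sd)
    }
    od[od < 0] <- 0
    list(table = kinetic_series(times, od, wells = names(cols),
                                unit = "OD", wavelength_nm = 600L),
         trajectory = traj, truth = truth)
  })
  names(out) <- scenarios
  out
}

#' Growth-ratio statistic from synthetic kinetic tables
#'
#' Recomputes [growth_ratio_statistic()] from plate-reader-format tables
#' instead of model trajectories: blank-corrects each scenario's table,
#' reads the per-strain signal at time `t`, and forms the per-strain
#' log10 same-well / separated ratios. Because the statistic is a ratio of
#' blank-corrected signals, the OD conversion factor cancels and, for
#' noise-free tables, the result equals the trajectory statistic.
#'
#' @param tab_same,tab_sep [kinetic_series()] OD tables from
#'   [gen_growth_experiment()] for the `same_well_positive` and
#'   `separated_coculture` scenarios.
#' @param t Comparison time, hours.
#' @param mode `"mean"` or `"per_strain"`.
#' @return As [growth_ratio_statistic()].
#' @export
growth_ratio_from_tables <- function(tab_same, tab_sep, t = 48,
                                     mode = c("mean", "per_strain")) {
  mode <- match.arg(mode)
  signal_at <- function(tab, strain) {
    blanks <- grep("\\.blank", tab$wells, value = TRUE)
    corrected <- blank_subtract(tab, blanks)
    col <- grep(paste0("\\.", strain, "$"), corrected$wells, value = TRUE)
    if (length(col) != 1) {
      stop("expected exactly one ", strain, " column, found ", length(col))
    }
    stats::approx(corrected$times, corrected$values[, col], xout = t)$y
  }
  per_strain <- vapply(c("dLys", "dIle"), function(s) {
    log10(signal_at(tab_same, s) / signal_at(tab_sep, s))
  }, numeric(1))
  if (mode == "mean") mean(per_strain) else per_strain
}

#' Write a synthetic dataset to disk
#'
#' Writes the kinetic table (CSV), the plate map (YAML) and the ground
#' truth (JSON) into a directory.
#'
#' @param dataset A [gen_dye_experiment()]-style list with `table`, `map`
#'   and `truth`.
#' @param dir Output directory (created if needed).
#' @param stem File-name stem.
#' @return Named character vector of the files written, invisibly.
#' @export
write_synthetic_dataset <- function(dataset, dir, stem = "synthetic") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(table = file.path(dir, paste0(stem, "_table.csv")),
             map = file.path(dir, paste0(stem, "_map.yaml")),
             truth = file.path(dir, paste0(stem, "_truth.json")))
  write_kinetic_table(dataset$table, paths["table"])
  if (!is.null(dataset$map)) write_plate_map(dataset$map, paths["map"])
  truth <- dataset$truth
  truth$strains <- lapply(truth$strains, unclass)
  jsonlite::write_json(unclass(truth), paths["truth"], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
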