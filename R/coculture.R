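#' Kinetic and stoichiometric parameters of one auxotrophic strain
#'
#' Parameters of the simplified dynamic-FBA growth law used for each
#' amino-acid auxotroph: Michaelis-Menten bounds on glucose and required
#' amino-acid uptake, biomass yields converting uptake into growth, and a
#' leakage stoichiometry `e_leak` giving the mmol of the partner's amino
#' acid released per gDW of biomass formed (leakage is strictly
#' growth-coupled; resting cells release nothing).
#'
#' The default amino-acid yield is derived from the per-cell amino-acid
#' requirement: `y_aa = (N_A * 1e-3 / aa_per_cell) * cell_dry_mass`, i.e.
#' cells formed per mmol of amino acid times dry mass per cell.
#'
#' @param name Strain label, conventionally `"dLys"` (lysine auxotroph) or
#'   `"dIle"` (isoleucine auxotroph).
#' @param required_aa Amino acid the strain cannot synthesize
#'   (`"lysine"` or `"isoleucine"`).
#' @param leaked_aa Amino acid the strain leaks (the partner's requirement);
#'   must differ from `required_aa`.
#' @param vmax_glc,vmax_aa Maximum uptake rates, mmol/(gDW h).
#' @param km_glc,km_aa Half-saturation constants, mmol/L.
#' @param y_glc Biomass yield on glucose, gDW/mmol.
#' @param y_aa Biomass yield on the required amino acid, gDW/mmol; derived
#'   from `aa_per_cell` when `NULL`.
#' @param e_leak Leakage stoichiometry, mmol leaked per gDW biomass formed.
#' @param aa_per_cell Amino-acid molecules required per cell (used to derive
#'   `y_aa`).
#' @param cell_dry_mass Dry mass per cell, gDW.
#' @return An object of class `strain_params`.
#' @export
strain_params <- function(name, required_aa = c("lysine", "isoleucine"),
                          leaked_aa = NULL,
                          vmax_glc = 10, km_glc = 0.05,
                          vmax_aa = 1, km_aa = 0.01,
                          y_glc = 0.09, y_aa = NULL, e_leak = 1,
                          aa_per_cell = NULL, cell_dry_mass = 2.8e-13) {
  required_aa <- match.arg(required_aa)
  if (is.null(leaked_aa)) {
    leaked_aa <- setdiff(c("lysine", "isoleucine"), required_aa)
  }
  if (identical(required_aa, leaked_aa)) {
    stop("a strain cannot require and leak the same amino acid")
  }
  if (is.null(aa_per_cell)) {
    aa_per_cell <- if (required_aa == "lysine") 1.1e8 else 7.5e7
  }
  if (is.null(y_aa)) {
    y_aa <- (6.022e23 * 1e-3 / aa_per_cell) * cell_dry_mass
  }
  stopifnot(vmax_glc > 0, km_glc > 0, vmax_aa > 0, km_aa > 0,
            y_glc > 0, y_aa > 0, e_leak >= 0)
  structure(list(name = name, required_aa = required_aa,
                 leaked_aa = leaked_aa,
                 vmax_glc = vmax_glc, km_glc = km_glc,
                 vmax_aa = vmax_aa, km_aa = km_aa,
                 y_glc = y_glc, y_aa = y_aa, e_leak = e_leak,
                 aa_per_cell = aa_per_cell, cell_dry_mass = cell_dry_mass),
            class = "strain_params")
}

#' @export
print.strain_params <- function(x, ...) {
  cat(sprintf("Strain %s: requires %s, leaks %s\n",
              x$name, x$required_aa, x$leaked_aa))
  cat(sprintf("  vmax %g / %g mmol/(gDW h), Km %g / %g mmol/L (glc / aa)\n",
              x$vmax_glc, x$vmax_aa, x$km_glc, x$km_aa))
  cat(sprintf("  yields %g / %.4g gDW/mmol (glc / aa), e_leak %g mmol/gDW\n",
              x$y_glc, x$y_aa, x$e_leak))
  invisible(x)
}

#' Default syntrophic strain pair
#'
#' The lysine auxotroph (leaks isoleucine) and the isoleucine auxotroph
#' (leaks lysine) with literature-style default kinetics.
#'
#' @param e_lys,e_ile Leakage stoichiometries (mmol/gDW) for the lysine
#'   leaked by `dIle` and the isoleucine leaked by `dLys`, respectively.
#'   Note the naming follows the *leaked* amino acid: `e_lys` is carried by
#'   the isoleucine auxotroph, which is the lysine producer.
#' @param ... Further arguments passed to both [strain_params()] calls
#'   (e.g. `vmax_glc`, `km_aa`, `y_glc`).
#' @return Named list of two `strain_params` (`dLys`, `dIle`).
#' @export
default_strains <- function(e_lys = 1, e_ile = 1, ...) {
  list(
    dLys = strain_params("dLys", required_aa = "lysine", e_leak = e_ile, ...),
    dIle = strain_params("dIle", required_aa = "isoleucine", e_leak = e_lys, ...)
  )
}

#' Liebig minimum-flux Monod growth rate
#'
#' Growth is set by the smaller of the two biomass fluxes each substrate
#' can sustain: `mu = min(y_glc vmax_glc C_glc / (km_glc + C_glc),
#' y_aa vmax_aa C_aa / (km_aa + C_aa))`, with `C_aa` the strain's required
#' amino acid. An auxotroph with no external amino acid has `mu = 0` (hard
#' auxotrophy).
#'
#' @param strain A [strain_params()].
#' @param glucose,aa Local concentrations in mmol/L (`aa` = the required
#'   amino acid).
#' @return Specific growth rate in 1/h.
#' @export
growth_rate <- function(strain, glucose, aa) {
  stopifnot(inherits(strain, "strain_params"), glucose >= 0, aa >= 0)
  mu_glc <- strain$y_glc * strain$vmax_glc * glucose / (strain$km_glc + glucose)
  mu_aa <- strain$y_aa * strain$vmax_aa * aa / (strain$km_aa + aa)
  pmin(mu_glc, mu_aa)
}

#' Assemble a coculture system for a standard experimental scenario
#'
#' Builds the compartment layout, inocula and medium of the standard
#' transwell experiments. All compartments are 250 uL by default; glucose
#' is 0.4% w/v (22.2 mmol/L at MW 180.16); the inoculum is an OD600 0.001
#' culture converted at 0.5 gDW/L per OD unit. Scenarios hosting both
#' strains additionally seed a trace of both amino acids (`aa_seed_mM`):
#' leakage is strictly growth-coupled, so an infinitesimal carryover of
#' amino acids from inoculum preparation is what lets mutual cross-feeding
#' start; monoculture scenarios get none, keeping their negative controls
#' flat.
#'
#' Scenarios:
#' \describe{
#'   \item{`separated_coculture`}{two compartments, one strain each,
#'     glucose both sides, membrane rate `d`.}
#'   \item{`same_well_positive`}{one compartment containing both strains
#'     (the positive control).}
#'   \item{`no_pore_control`}{as `separated_coculture` but `d = 0`.}
#'   \item{`mono_supplement_across`}{one strain on the left, its required
#'     amino acid dosed in the right compartment (default: the
#'     [supplement_concentration()] dose for a 1e9-cell yield).}
#'   \item{`mono_no_partner`}{one strain, glucose only (negative control).}
#' }
#'
#' @param scenario One of the scenario names above.
#' @param strains Named list with `dLys` and `dIle` [strain_params()].
#' @param d Membrane diffusion rate, L/h.
#' @param volume Compartment volume, L.
#' @param glucose_mM Initial glucose concentration, mmol/L.
#' @param inoculum_od Inoculum OD600 per strain.
#' @param od_to_gdw_per_l Biomass conversion factor, gDW/L per OD600 unit.
#' @param aa_seed_mM Trace amino-acid carryover in coculture scenarios,
#'   mmol/L.
#' @param mono_strain Which strain a monoculture scenario uses.
#' @param supplement_mM Amino-acid dose for `mono_supplement_across`
#'   (mmol/L); default is the 1e9-cell-yield dose for the strain's
#'   requirement.
#' @return An object of class `coculture_system`: list with `compartments`
#'   (each with `volume`, `biomass`, `amounts`), `strains`, and `d`.
#' @export
build_experiment <- function(scenario = c("separated_coculture",
                                          "same_well_positive",
                                          "no_pore_control",
                                          "mono_supplement_across",
                                          "mono_no_partner"),
                             strains = default_strains(),
                             d = 3.88e-5, volume = 2.5e-4,
                             glucose_mM = 22.2, inoculum_od = 0.001,
                             od_to_gdw_per_l = 0.5, aa_seed_mM = 1e-4,
                             mono_strain = c("dLys", "dIle"),
                             supplement_mM = NULL) {
  scenario <- match.arg(scenario)
  mono_strain <- match.arg(mono_strain)
  stopifnot(volume > 0, d >= 0)
  b0 <- inoculum_od * od_to_gdw_per_l * volume  # gDW per compartment
  glc0 <- glucose_mM * volume                    # mmol
  seed0 <- aa_seed_mM * volume

  empty_comp <- function() {
    list(volume = volume,
         biomass = c(dLys = 0, dIle = 0),
         amounts = c(glucose = glc0, lysine = 0, isoleucine = 0))
  }
  comps <- switch(scenario,
    separated_coculture = {
      c1 <- empty_comp(); c2 <- empty_comp()
      c1$biomass["dLys"] <- b0; c2$biomass["dIle"] <- b0
      c1$amounts[c("lysine", "isoleucine")] <- seed0
      c2$amounts[c("lysine", "isoleucine")] <- seed0
      list(c1, c2)
    },
    no_pore_control = {
      c1 <- empty_comp(); c2 <- empty_comp()
      c1$biomass["dLys"] <- b0; c2$biomass["dIle"] <- b0
      c1$amounts[c("lysine", "isoleucine")] <- seed0
      c2$amounts[c("lysine", "isoleucine")] <- seed0
      list(c1, c2)
    },
    same_well_positive = {
      c1 <- empty_comp()
      c1$biomass[c("dLys", "dIle")] <- b0
      c1$amounts[c("lysine", "isoleucine")] <- seed0
      list(c1)
    },
    mono_supplement_across = {
      c1 <- empty_comp(); c2 <- empty_comp()
      c1$biomass[mono_strain] <- b0
      req <- strains[[mono_strain]]$required_aa
      if (is.null(supplement_mM)) {
        supplement_mM <- 1000 * supplement_concentration(
          strains[[mono_strain]]$aa_per_cell, 1e9, volume)
      }
      c2$amounts[req] <- supplement_mM * volume
      list(c1, c2)
    },
    mono_no_partner = {
      c1 <- empty_comp()
      c1$biomass[mono_strain] <- b0
      list(c1)
    })
  d_eff <- if (scenario == "no_pore_control") 0 else d
  structure(list(compartments = comps, strains = strains, d = d_eff,
                 scenario = scenario),
            class = "coculture_system")
}

#' @export
print.coculture_system <- function(x, ...) {
  cat(sprintf("Coculture system (%s): %d compartment(s), d = %.4g L/h\n",
              x$scenario, length(x$compartments), x$d))
  for (i in seq_along(x$compartments)) {
    cp <- x$compartments[[i]]
    cat(sprintf("  comp %d (%.3g L): biomass dLys %.3g, dIle %.3g gDW; %s\n",
                i, cp$volume, cp$biomass["dLys"], cp$biomass["dIle"],
                paste(sprintf("%s %.4g mmol", names(cp$amounts), cp$amounts),
                      collapse = ", ")))
  }
  invisible(x)
}

# Pack system into the state / parameter vectors the compiled RHS expects.
.met_idx <- c(glucose = 0, lysine = 1, isoleucine = 2)

.pack_state <- function(sys) {
  comps <- sys$compartments
  get_comp <- function(i) {
    if (i <= length(comps)) comps[[i]] else
      list(volume = comps[[1]]$volume,
           biomass = c(dLys = 0, dIle = 0),
           amounts = c(glucose = 0, lysine = 0, isoleucine = 0))
  }
  c1 <- get_comp(1); c2 <- get_comp(2)
  c(B1.dLys = unname(c1$biomass["dLys"]), B1.dIle = unname(c1$biomass["dIle"]),
    B2.dLys = unname(c2$biomass["dLys"]), B2.dIle = unname(c2$biomass["dIle"]),
    N1.glucose = unname(c1$amounts["glucose"]),
    N1.lysine = unname(c1$amounts["lysine"]),
    N1.isoleucine = unname(c1$amounts["isoleucine"]),
    N2.glucose = unname(c2$amounts["glucose"]),
    N2.lysine = unname(c2$amounts["lysine"]),
    N2.isoleucine = unname(c2$amounts["isoleucine"]))
}

.pack_parms <- function(sys) {
  comps <- sys$compartments
  v2 <- if (length(comps) > 1) comps[[2]]$volume else comps[[1]]$volume
  strain_block <- function(s) {
    c(s$vmax_glc, s$km_glc, s$vmax_aa, s$km_aa, s$y_glc, s$y_aa, s$e_leak,
      .met_idx[s$required_aa], .met_idx[s$leaked_aa])
  }
  unname(c(sys$d, comps[[1]]$volume, v2, length(comps),
           strain_block(sys$strains$dLys), strain_block(sys$strains$dIle)))
}

#' Simulate coculture growth and metabolite dynamics
#'
#' Integrates the compartment ODEs: biomass grows at the Liebig-Monod rate
#' ([growth_rate()]), the limiting and non-limiting substrates are drawn
#' down stoichiometrically at `mu/y`, the partner's amino acid is leaked at
#' `e_leak * mu * B`, and every metabolite diffuses across the membrane at
#' `d * (C_other - C_this)` in two-compartment systems. The integrator is
#' `deSolve::lsode` (stiff-capable BDF, adaptive) with a maximum step of
#' 0.0025 h and an absolute tolerance of 1e-12 on amounts; the hard `min`
#' in the growth law is left unsmoothed. States are floored at zero after
#' integration; an excursion below -1e-9 aborts with a step-size error.
#'
#' @param sys A [build_experiment()] system.
#' @param t_end Horizon in hours.
#' @param times Output time grid (hours); default every 0.25 h.
#' @param hmax Maximum integrator step, h.
#' @param atol,rtol Solver tolerances.
#' @return An object of class `coculture_trajectory`: list with `times`,
#'   `states` (matrix of biomass/amount columns) and the `system`.
#' @export
simulate_coculture <- function(sys, t_end = 96,
                               times = seq(0, t_end, by = 0.25),
                               hmax = 0.0025, atol = 1e-12, rtol = 1e-8) {
  stopifnot(inherits(sys, "coculture_system"), t_end > 0)
  y0 <- .pack_state(sys)
  parms <- .pack_parms(sys)
  sol <- deSolve::lsode(y0, times, func = "coculture_deriv", parms = parms,
                        dllname = "coculture", initfunc = "coculture_initmod",
                        hmax = hmax, atol = atol, rtol = rtol,
                        maxsteps = 1e6)
  if (anyNA(unclass(sol))) {
    stop("coculture ODE solver produced non-finite states")
  }
  if (attr(sol, "istate")[1] < 0) {
    stop("coculture ODE solver failed: istate = ", attr(sol, "istate")[1])
  }
  states <- unclass(sol)[, -1, drop = FALSE]
  if (min(states) < -1e-9) {
    stop(sprintf(
      "negative state excursion (%.3g): step size too coarse for this system",
      min(states)))
  }
  states[states < 0] <- 0
  structure(list(times = as.numeric(unclass(sol)[, 1]), states = states,
                 system = sys),
            class = "coculture_trajectory")
}

# Pure-R reference implementation of the same derivative, used as an
# independent check on the compiled code.
coculture_deriv_r <- function(t, y, sys) {
  comps <- length(sys$compartments)
  vols <- c(sys$compartments[[1]]$volume,
            if (comps > 1) sys$compartments[[2]]$volume else
              sys$compartments[[1]]$volume)
  ydot <- numeric(10)
  conc <- function(w, m) max(y[4 + 3 * (w - 1) + m + 1 - 1], 0) / vols[w]
  for (w in seq_len(comps)) {
    for (s in 1:2) {
      st <- sys$strains[[s]]
      B <- max(y[2 * (w - 1) + s], 0)
      cg <- conc(w, .met_idx["glucose"] + 1)
      cr <- conc(w, .met_idx[st$required_aa] + 1)
      mu <- min(st$y_glc * st$vmax_glc * cg / (st$km_glc + cg),
                st$y_aa * st$vmax_aa * cr / (st$km_aa + cr))
      ydot[2 * (w - 1) + s] <- ydot[2 * (w - 1) + s] + mu * B
      ig <- 4 + 3 * (w - 1) + 1
      ir <- 4 + 3 * (w - 1) + .met_idx[st$required_aa] + 1
      il <- 4 + 3 * (w - 1) + .met_idx[st$leaked_aa] + 1
      ydot[ig] <- ydot[ig] - mu / st$y_glc * B
      ydot[ir] <- ydot[ir] - mu / st$y_aa * B
      ydot[il] <- ydot[il] + st$e_leak * mu * B
    }
  }
  if (comps == 2) {
    for (m in 0:2) {
      flux <- sys$d * (max(y[5 + m], 0) / vols[1] - max(y[8 + m], 0) / vols[2])
      ydot[5 + m] <- ydot[5 + m] - flux
      ydot[8 + m] <- ydot[8 + m] + flux
    }
  }
  ydot
}

#' @export
print.coculture_trajectory <- function(x, ...) {
  cat(sprintf("Coculture trajectory (%s): %d timepoints over %.3g h\n",
              x$system$scenario, length(x$times), max(x$times)))
  final <- x$states[nrow(x$states), ]
  cat(sprintf("  final biomass: dLys %.4g, dIle %.4g gDW (total)\n",
              sum(final[c("B1.dLys", "B2.dLys")]),
              sum(final[c("B1.dIle", "B2.dIle")])))
  invisible(x)
}

#' @export
as.data.frame.coculture_trajectory <- function(x, ...) {
  data.frame(time = x$times, x$states, check.names = FALSE)
}

#' @export
plot.coculture_trajectory <- function(x, what = c("biomass", "metabolites"),
                                      log = "", ...) {
  what <- match.arg(what)
  if (what == "biomass") {
    b_lys <- rowSums(x$states[, c("B1.dLys", "B2.dLys"), drop = FALSE])
    b_ile <- rowSums(x$states[, c("B1.dIle", "B2.dIle"), drop = FALSE])
    graphics::matplot(x$times, cbind(b_lys, b_ile), type = "l", lty = 1,
                      col = c("steelblue", "forestgreen"), log = log,
                      xlab = "time (h)", ylab = "biomass (gDW)", ...)
    graphics::legend("topleft", c("dLys", "dIle"), lty = 1,
                     col = c("steelblue", "forestgreen"), bty = "n")
  } else {
    cols <- grep("^N", colnames(x$states), value = TRUE)
    graphics::matplot(x$times, x$states[, cols], type = "l", lty = 1,
                      log = log, xlab = "time (h)", ylab = "amount (mmol)",
                      ...)
    graphics::legend("right", cols, lty = 1, col = seq_along(cols),
                     bty = "n")
  }
  invisible(x)
}

#' Biomass of a strain at a given time
#'
#' Linear interpolation of the strain's total biomass (summed over the
#' compartments it occupies) along a trajectory.
#'
#' @param traj A [simulate_coculture()] trajectory.
#' @param t Time in hours, inside the trajectory span.
#' @param strain `"dLys"` or `"dIle"`.
#' @return Biomass in gDW.
#' @export
yield_at <- function(traj, t, strain = c("dLys", "dIle")) {
  stopifnot(inherits(traj, "coculture_trajectory"))
  strain <- match.arg(strain)
  if (t < min(traj$times) || t > max(traj$times)) {
    stop("t outside the trajectory span")
  }
  cols <- paste0(c("B1.", "B2."), strain)
  total <- rowSums(traj$states[, cols, drop = FALSE])
  stats::approx(traj$times, total, xout = t)$y
}

#' Same-well vs membrane-separated growth-ratio statistic
#'
#' The summary statistic used for inference: the log10 ratio of a strain's
#' biomass yield at time `t` grown in the same well as its partner
#' (positive control) over its yield grown membrane-separated. Working on
#' a ratio of yields makes the statistic unit-free, so blank-corrected OD
#' and gDW give the same number. `mode = "mean"` averages the two strains'
#' statistics; `mode = "per_strain"` returns both.
#'
#' @param traj_same Trajectory of the same-well positive control.
#' @param traj_sep Trajectory of the membrane-separated coculture.
#' @param t Comparison time, hours (default 48).
#' @param mode `"mean"` or `"per_strain"`.
#' @return A single number (`mean`) or named vector `c(dLys=, dIle=)`.
#' @export
growth_ratio_statistic <- function(traj_same, traj_sep, t = 48,
                                   mode = c("mean", "per_strain")) {
  mode <- match.arg(mode)
  per_strain <- vapply(c("dLys", "dIle"), function(s) {
    ys <- yield_at(traj_same, t, s)
    yp <- yield_at(traj_sep, t, s)
    if (ys <= 0 || yp <= 0) {
      stop("zero yield at t = ", t, " for ", s, ": statistic undefined")
    }
    log10(ys / yp)
  }, numeric(1))
  if (mode == "mean") mean(per_strain) else per_strain
}
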