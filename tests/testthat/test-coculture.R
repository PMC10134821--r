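test_that("the Liebig-Monod growth law takes the minimum limiting flux", {
  st <- strain_params("dLys", required_aa = "lysine")
  # hard auxotrophy: no amino acid, no growth
  expect_equal(growth_rate(st, glucose = 22.2, aa = 0), 0)
  # both saturating: min of the two asymptotic biomass fluxes
  expect_equal(growth_rate(st, glucose = 1e6, aa = 1e6),
               min(st$y_glc * st$vmax_glc, st$y_aa * st$vmax_aa),
               tolerance = 1e-4)
  # amino acid at half-saturation with glucose saturating
  st2 <- strain_params("dLys", required_aa = "lysine", y_aa = 0.05)
  expect_equal(growth_rate(st2, glucose = 1e6, aa = st2$km_aa),
               st2$y_aa * st2$vmax_aa / 2, tolerance = 1e-6)
})

test_that("derived amino-acid yields follow the per-cell requirement", {
  st <- default_strains()
  expect_equal(st$dLys$y_aa, 6.022e20 / 1.1e8 * 2.8e-13, tolerance = 1e-12)
  expect_equal(st$dIle$y_aa, 6.022e20 / 7.5e7 * 2.8e-13, tolerance = 1e-12)
  expect_equal(st$dLys$required_aa, "lysine")
  expect_equal(st$dLys$leaked_aa, "isoleucine")
  expect_error(strain_params("x", required_aa = "lysine",
                             leaked_aa = "lysine"), "cannot require and leak")
})

test_that("scenario builders lay out compartments as designed", {
  sep <- build_experiment("separated_coculture")
  expect_length(sep$compartments, 2)
  expect_gt(sep$d, 0)
  expect_equal(sep$compartments[[1]]$biomass[["dLys"]], 1.25e-7)
  expect_equal(sep$compartments[[2]]$biomass[["dIle"]], 1.25e-7)
  expect_equal(sep$compartments[[1]]$amounts[["glucose"]],
               sep$compartments[[2]]$amounts[["glucose"]])

  npc <- build_experiment("no_pore_control")
  expect_equal(npc$d, 0)
  npc$d <- sep$d; npc$scenario <- sep$scenario
  expect_equal(npc, sep)  # differs from separated only by d

  pos <- build_experiment("same_well_positive")
  expect_length(pos$compartments, 1)
  expect_true(all(pos$compartments[[1]]$biomass > 0))

  mono <- build_experiment("mono_supplement_across", mono_strain = "dLys")
  expect_equal(mono$compartments[[2]]$amounts[["lysine"]] / 2.5e-4,
               0.731, tolerance = 1e-3)  # mmol/L dosed across the membrane
  expect_equal(mono$compartments[[2]]$biomass[["dLys"]], 0)

  neg <- build_experiment("mono_no_partner", mono_strain = "dIle")
  expect_length(neg$compartments, 1)
  expect_equal(sum(neg$compartments[[1]]$amounts[c("lysine", "isoleucine")]),
               0)
  expect_error(build_experiment("warp_drive"))
})

test_that("negative controls stay at the inoculum", {
  tr <- simulate_coculture(build_experiment("mono_no_partner"), t_end = 48,
                           times = c(0, 24, 48))
  expect_equal(yield_at(tr, 48, "dLys"), yield_at(tr, 0, "dLys"),
               tolerance = 1e-9)

  # no pores and no supplement: growth capped by the trace carryover only
  tr2 <- simulate_coculture(build_experiment("no_pore_control"), t_end = 48,
                            times = c(0, 48))
  for (s in c("dLys", "dIle")) {
    expect_lt(yield_at(tr2, 48, s) / yield_at(tr2, 0, s), 2)
  }
})

test_that("supplemented monoculture reaches the theoretical 1e9-cell yield", {
  tr <- simulate_coculture(build_experiment("mono_supplement_across"),
                           t_end = 96, times = seq(0, 96, 4))
  final <- yield_at(tr, 96, "dLys")
  # 0.731 mmol/L x 250 uL x y_aa == 1e9 cells x 2.8e-13 gDW
  expect_equal(final, 1e9 * 2.8e-13, tolerance = 0.01)
})

test_that("glucose drawdown converts to biomass at the stated yield", {
  # single well, lysine in excess so glucose is the limiting substrate
  sys <- build_experiment("mono_no_partner", mono_strain = "dLys")
  sys$compartments[[1]]$amounts["lysine"] <- 50 * 2.5e-4
  tr <- simulate_coculture(sys, t_end = 48, times = seq(0, 48, 2))
  df <- as.data.frame(tr)
  biomass_formed <- df$B1.dLys[nrow(df)] - df$B1.dLys[1]
  glc_used <- df$N1.glucose[1] - df$N1.glucose[nrow(df)]
  st <- default_strains()$dLys
  expect_equal(biomass_formed, glc_used * st$y_glc, tolerance = 1e-6)
  # glucose exhausted: biomass equals inoculum + glucose x yield
  expect_equal(df$B1.dLys[nrow(df)],
               1.25e-7 + 22.2 * 2.5e-4 * st$y_glc, tolerance = 1e-4)
})

test_that("compiled and reference derivatives agree at random states", {
  set.seed(31)
  sys <- build_experiment("separated_coculture")
  p <- coculture:::.pack_parms(sys)
  for (i in 1:20) {
    y <- runif(10, 0, 1e-3)
    r_side <- coculture:::coculture_deriv_r(0, y, sys)
    c_side <- deSolve::lsoda(y, c(0, 1e-9), func = "coculture_deriv",
                             parms = p, dllname = "coculture",
                             initfunc = "coculture_initmod")
    # derivative check via a tiny Euler step
    expect_equal(unname((unclass(c_side)[2, -1] - y) / 1e-9), r_side,
                 tolerance = 1e-5)
  }
})

test_that("mirrored systems produce mirrored trajectories", {
  st <- default_strains(e_lys = 2, e_ile = 0.5)
  sys <- build_experiment("separated_coculture", strains = st)
  # swap compartments and strain labels consistently
  sw <- sys
  sw$compartments <- sys$compartments[c(2, 1)]
  tt <- seq(0, 48, 1)
  a <- simulate_coculture(sys, t_end = 48, times = tt)$states
  b <- simulate_coculture(sw, t_end = 48, times = tt)$states
  mirror <- c("B2.dLys", "B2.dIle", "B1.dLys", "B1.dIle",
              "N2.glucose", "N2.lysine", "N2.isoleucine",
              "N1.glucose", "N1.lysine", "N1.isoleucine")
  expect_lt(max(abs(a - b[, mirror])), 1e-10)
})

test_that("states remain non-negative for draws across the prior box", {
  set.seed(8)
  for (i in 1:5) {
    e <- 10^runif(1, -2, 1)
    d <- 10^runif(1, log10(1.227e-5), log10(1.227e-4))
    st <- default_strains(e_lys = e, e_ile = e)
    tr <- simulate_coculture(build_experiment("separated_coculture",
                                              strains = st, d = d),
                             t_end = 48, times = c(0, 24, 48))
    expect_true(all(tr$states >= 0))
  }
})

test_that("yield interpolation matches closed-form exponential growth", {
  # constant-rate segment: supplemented culture in early exponential phase
  sys <- build_experiment("mono_no_partner", mono_strain = "dLys")
  sys$compartments[[1]]$amounts["lysine"] <- 100 * 2.5e-4
  tr <- simulate_coculture(sys, t_end = 4, times = seq(0, 4, 0.05))
  mu <- growth_rate(default_strains()$dLys, 22.2, 100)
  t_mid <- 2.025  # off the output grid
  expect_equal(yield_at(tr, t_mid, "dLys"), 1.25e-7 * exp(mu * t_mid),
               tolerance = 1e-3)
  expect_equal(yield_at(tr, 0, "dLys"), 1.25e-7)
  expect_error(yield_at(tr, 5, "dLys"), "span")
})

test_that("the growth-ratio statistic obeys its log identities", {
  same <- simulate_coculture(build_experiment("same_well_positive"),
                             t_end = 48, times = c(0, 48))
  sep <- simulate_coculture(build_experiment("separated_coculture"),
                            t_end = 48, times = c(0, 48))
  per <- growth_ratio_statistic(same, sep, mode = "per_strain")
  expect_named(per, c("dLys", "dIle"))
  expect_equal(growth_ratio_statistic(same, sep, mode = "mean"), mean(per))
  # identical trajectories -> 0
  expect_equal(growth_ratio_statistic(same, same), 0)
  # a 100x yield ratio -> statistic of exactly 2
  boosted <- same
  boosted$states <- same$states * 100
  expect_equal(growth_ratio_statistic(boosted, same), 2, tolerance = 1e-12)
})

test_that("fast diffusion approaches the merged single-well limit", {
  # As d grows, the separated pair behaves like one 500-uL well holding
  # both strains at half density (same totals of glucose, volume, biomass).
  merged_gap <- function(d, e) {
    st <- default_strains(e_lys = e, e_ile = e)
    sep <- simulate_coculture(build_experiment("separated_coculture",
                                               strains = st, d = d),
                              t_end = 48, times = c(0, 48))
    merged <- simulate_coculture(build_experiment("same_well_positive",
                                                  strains = st,
                                                  volume = 5e-4,
                                                  inoculum_od = 5e-4),
                                 t_end = 48, times = c(0, 48))
    max(vapply(c("dLys", "dIle"), function(s) {
      abs(yield_at(sep, 48, s) / yield_at(merged, 48, s) - 1)
    }, numeric(1)))
  }
  expect_lt(merged_gap(1e-2, 10), 0.01)
  expect_lt(merged_gap(1e-1, 1), 0.01)
  # and the gap shrinks as d grows
  expect_lt(merged_gap(1e-1, 1), merged_gap(1e-2, 1))
})
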