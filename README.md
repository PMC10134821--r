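# coculture

Quantitative analysis of microbial interactions measured in
transwell-style coculture plates, where pairs of wells exchange small
molecules through a porous membrane while a plate reader tracks each
population's optical density independently. The package was built around
the engineered syntrophy between two *E. coli* amino-acid auxotrophs —
ΔLys (requires lysine, leaks isoleucine) and ΔIle (requires isoleucine,
leaks lysine) — but its pieces are generic:

* **Plate I/O and calibration** — wide kinetic CSV tables in and out,
  per-timepoint blank subtraction, ordinary-least-squares calibration
  lines (`OD = slope·C + intercept`) and their inversion, dilution
  fractions, and amino-acid supplementation doses for a target cell
  yield.
* **Two-well diffusion** — the lumped gradient-driven model
  `dN_L/dt = −d (C_L − C_R)` with analytic exponential solution, numeric
  cross-check, and a nonlinear least-squares estimator for the membrane
  rate `d` (L/h) from concentration time courses.
* **Syntrophic coculture ODE model** — Michaelis–Menten-bounded uptake,
  Liebig minimum-flux Monod growth `μ = min(y_glc v_glc C/(K+C),
  y_aa v_aa C/(K+C))`, growth-proportional amino-acid leakage
  (`e` mmol per gDW formed), and cross-membrane diffusion of every
  metabolite; compiled right-hand side, stiff adaptive integration at a
  0.0025-h maximum step.
* **Rejection ABC** — log-uniform/point priors over leakage and
  diffusion, the 48-h statistic `S = log10(yield_same / yield_separated)`,
  and acceptance within `k` standard deviations of the observed mean,
  with shipped presets for the equal-leakage, unequal-leakage and
  noisy-prior analyses.
* **Synthetic data** — generators that emulate the plate-reader exports
  (72-h dye kinetics, destructive amino-acid sampling, 96-h growth
  curves) with recorded ground truth and seeds, so the whole pipeline is
  testable offline.

## Worked example

Generate a synthetic dye-diffusion experiment, calibrate, and estimate
the membrane diffusion rate for a 0.1-µm pair:

```r
library(coculture)

truth <- synthetic_truth(seed = 42)        # d = 3.88e-5 L/h for 0.1 um
dye   <- gen_dye_experiment(truth)
cal   <- fit_calibration(data.frame(
  concentration = seq(0.45, 0, by = -0.05),
  od            = 0.05 + seq(0.45, 0, by = -0.05)))
cal
#> Linear calibration: OD = slope * C + intercept
#>   slope     1 OD per unit concentration
#>   intercept 0.05 OD
#>   r-squared 1.000000  (n = 10 standards)

conc <- apply_calibration(dye$table, cal)
pair <- dye$map$pairs[dye$map$pairs$pore_size == "0.1", ][1, ]
fit_diffusion_rate(subset_wells(conc, c(pair$left, pair$right)),
                   c_left0 = 0.4)
#> Two-well diffusion rate fit
#>   d_hat    = 3.85023e-05 L/h  (side: pooled)
#>   rate     = 0.308018 1/h (exponential decay constant)
#>   residual norm = 0.118 mmol/L
```

The estimate lands within 1% of the generating truth despite 0.005-OD
measurement noise on 289 timepoints.

Simulate the syntrophic pair and compute the same-well vs
membrane-separated growth statistic at 48 h:

```r
same <- simulate_coculture(build_experiment("same_well_positive"),
                           t_end = 48, times = c(0, 48))
sep  <- simulate_coculture(build_experiment("separated_coculture"),
                           t_end = 48, times = c(0, 48))
growth_ratio_statistic(same, sep, mode = "per_strain")
#>     dLys     dIle
#> 2.739454 2.797759
```

At the default leakage (1 mmol/gDW) and the measured diffusion rate
(3.88e-5 L/h) the membrane suppresses each strain's 48-h yield by almost
three orders of magnitude relative to shared-well growth — the
diffusion-limited regime.

Infer the leakage stoichiometry with the shipped equal-leakage preset
(observed statistic 1.14, sd 0.235, `k = 2`):

```r
post <- run_rejection(abc_preset("equal"), 300, seed = 1)
post
#> Rejection-ABC posterior: 300 draws (300 simulated ok), 8 accepted (2.7%)
summary(post)
#> Acceptance rate: 2.67%
#>  parameter n_accepted log10_median log10_q25 log10_q75 log10_q2.5 log10_q97.5
#>          d          8      -4.5009   -4.6714    -4.355    -4.7782     -4.1266
#>     e_leak          8       0.3501    0.2869     0.419     0.1972      0.4848
```

The observed growth ratio is compatible with leakage around
10^0.35 ≈ 2 mmol per gDW of biomass formed. `plot(post)` overlays the
prior and posterior leakage histograms; `statistic_map(post)` exports the
(d, e, S) triples behind a parameter-space heat map.

See `vignettes/coculture-methods.Rmd` for the model equations,
parameter defaults and their rationale, numerical choices, and known
limitations.

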