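---
title: "Models and inference for membrane-separated cocultures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and inference for membrane-separated cocultures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coculture)
```

## The experimental system

Transwell-style coculture plates hold pairs of wells separated by a porous
track-etched membrane: each well carries its own culture, a plate reader
measures each population's optical density independently, and small
molecules — dyes used for characterisation, or the amino acids two
auxotrophic *E. coli* strains exchange — diffuse across the membrane.
This package implements the computational stack such experiments need:

1. plate-reader kinetic-table handling (blank subtraction, linear
   calibration, design arithmetic such as dilution fractions and
   amino-acid doses),
2. a lumped two-compartment diffusion model and an estimator for the
   membrane's diffusion rate,
3. a dynamic model of the syntrophic auxotroph pair (Michaelis–Menten
   uptake, Liebig minimum-flux Monod growth, growth-proportional leakage),
4. rejection approximate Bayesian computation (ABC) over the leakage and
   diffusion parameters, and
5. a synthetic-data generator that emulates the plate-reader exports with
   known ground truth, so every stage can be exercised and validated
   without any downloads.

## Two-well diffusion

Both wells are treated as well-mixed compartments. For amounts $N_L, N_R$
(mmol) and concentrations $C = N/V$ (mmol/L), the flux across the membrane
is proportional to the concentration difference:

$$\frac{dN_L}{dt} = -d\,(C_L - C_R), \qquad
  \frac{dN_R}{dt} = +d\,(C_L - C_R).$$

The membrane's area and thickness are absorbed into the single rate $d$,
which therefore carries units of L/h (so that $d \cdot \Delta C$ is a flux
in mmol/h) rather than the units of a classic diffusion coefficient. Each
well's deviation from the amount-weighted equilibrium decays as
$e^{-rt}$ with $r = d\,(1/V_L + 1/V_R)$ — $2d/V$ for the equal 250-µL
wells used throughout. `analytic_two_well()` evaluates this closed form
and `simulate_diffusion()` integrates the ODEs numerically; the test suite
holds them to a sup-norm of $10^{-8}$ mmol/L over a 72-h, 15-min schedule.

`fit_diffusion_rate()` estimates $d$ from a calibrated concentration time
course by nonlinear least squares on the deviation from equilibrium,
$D(t) = a e^{bt}$, returning $\hat d = -b/(1/V_L + 1/V_R)$. Choices worth
stating explicitly:

* **Pooled fitting (default).** The left-well deviation and the negated
  right-well deviation share the same amplitude and decay constant for
  equal volumes, so both are stacked into one regression. Per-side fits
  (`side = "left"` / `"right"`) exist because a first-order loss of
  material from the input well (dye settling or sequestration in the
  membrane) biases the input-side estimate upward relative to the
  receiver side — the generator can inject such a loss term
  (`loss_rate`) to reproduce that asymmetry.
* **Initialisation and stopping.** The exponential fit is started from a
  log-linear regression of $|D(t)|$ over the first half of the series and
  iterated to a relative parameter change below $10^{-10}$ (at most 500
  iterations). A fitted $b > 0$ (growing deviation) is returned flagged
  with a warning rather than silently; a series that starts at
  equilibrium has no identifiable rate and errors.
* **Units.** mmol, mmol/L, L and h throughout, so $d$ is in L/h.

## The syntrophic coculture model

Two engineered auxotrophs — ΔLys (cannot make lysine, leaks isoleucine)
and ΔIle (cannot make isoleucine, leaks lysine) — grow on glucose minimal
medium and depend on each other's leakage. Per compartment $w$ and strain
$s$ with biomass $B$ (gDW):

$$\mu_s = \min\!\left(
   y_{glc} v_{glc} \frac{C_{glc}}{K_{glc} + C_{glc}},\;
   y_{aa} v_{aa} \frac{C_{aa}}{K_{aa} + C_{aa}}\right), \qquad
  \frac{dB}{dt} = \mu_s B,$$

with $C_{aa}$ the strain's required amino acid. Substrates are drawn down
stoichiometrically at $\mu/y$ (no luxury uptake or overflow), the
partner's amino acid is released at $e\,\mu B$ — leakage is strictly
growth-coupled, mmol per gDW of biomass *formed* — and every metabolite
diffuses between compartments at $d(C_{other} - C_{this})$. This is a
minimal dynamic-FBA-style model: the hard minimum is deliberately not
smoothed, and there are no death, maintenance or lag terms.

### Parameters and defaults

| parameter | default | units | note |
|---|---|---|---|
| $v_{glc}$, $K_{glc}$ | 10, 0.05 | mmol/(gDW·h), mmol/L | literature-scale glucose uptake |
| $v_{aa}$, $K_{aa}$ | 1, 0.01 | mmol/(gDW·h), mmol/L | amino-acid uptake |
| $y_{glc}$ | 0.09 | gDW/mmol | ≈ 0.5 g/g glucose |
| $y_{aa}$ | derived | gDW/mmol | $(N_A \cdot 10^{-3}/n_{aa}) \cdot m_{cell}$ |
| $n_{aa}$ | 1.1e8 (lys), 7.5e7 (ile) | molecules/cell | per-cell requirement |
| $m_{cell}$ | 2.8e-13 | gDW/cell | dry mass per cell |
| $e$ | 1 | mmol/gDW | leakage stoichiometry (the inferred quantity) |
| $d$ | 3.88e-5 | L/h | measured mean amino-acid rate, 0.1-µm membrane |

Initial conditions mirror the bench protocol: 0.4% w/v glucose
(22.2 mmol/L at MW 180.16) in every 250-µL compartment, and an OD600 0.001
inoculum converted at 0.5 gDW/L per OD unit (1.25e-7 gDW per well). All
conversion factors are arguments.

The derived $y_{aa}$ ties the model to the supplementation arithmetic: a
monoculture given the 0.731 mmol/L lysine dose computed by
`supplement_concentration(1.1e8, 1e9, 2.5e-4)` reaches exactly the
theoretical yield of $10^9$ cells ($2.8 \times 10^{-4}$ gDW), which the
test suite checks by simulation.

### Bootstrapping cross-feeding

Because leakage is proportional to biomass *formed* and an auxotroph with
no external amino acid has $\mu = 0$, a coculture started with zero
amino acids is a fixed point: nothing can ever grow. Real inocula carry a
trace of amino acids from their preparation, and the model needs that
trace for cross-feeding to start. Scenarios hosting both strains
(`separated_coculture`, `same_well_positive`, `no_pore_control`) therefore
seed both amino acids at `aa_seed_mM = 1e-4` mmol/L (0.1 µM, the order of
carryover surviving a wash); monoculture scenarios get none, which keeps
the negative controls exactly flat, as observed on the bench. The seed is
small enough that subcritical-leakage systems gain well under one doubling
from it, yet sufficient to ignite the exponential mutual feeding when
leakage is high.

A consequence worth knowing: sustained mutual growth requires the
amplification loop to exceed unity, $e_{lys} e_{ile} y_{aa,lys}
y_{aa,ile} > 1$ — about $e^* \approx 0.54$ mmol/gDW for equal leakage at
the defaults. Below that threshold the 48-h growth statistic is
insensitive to $e$, which bounds what any inference can recover there.

### Scenarios

`build_experiment()` encodes the standard layouts: membrane-separated
coculture, same-well positive control (a single 250-µL well holding both
strains, matching the experimental control), the no-pore control
($d = 0$), a monoculture with its amino acid dosed across the membrane,
and the unsupplemented negative control. The comparison statistic is

$$S_s = \log_{10} \frac{\text{yield}_{same}(s, 48\,h)}
                        {\text{yield}_{sep}(s, 48\,h)},$$

per strain or averaged (`growth_ratio_statistic()`). Being a ratio of
yields it is unit-free: blank-corrected OD and gDW give the same number,
which is what lets experimental OD ratios be compared with simulated
biomass ratios without any biomass calibration.

Because the separated pair holds twice the total glucose and volume of the
single-well positive control, the exact large-$d$ limit of the separated
system is not the positive control itself but a merged 500-µL well holding
both strains at half density (same totals of everything). The test suite
verifies that limit to within 1%, and it explains why $S$ at saturating
leakage and diffusion settles near $\log_{10}(1/2) \approx -0.3$ rather
than 0.

### Numerics

`deSolve::lsode` (stiff BDF) with the maximum step fixed at 0.0025 h,
absolute tolerance $10^{-12}$ on amounts and relative tolerance
$10^{-8}$. The hard minimum in the growth law creates a sharp corner at
substrate exhaustion; `lsoda`'s stiffness-switching logic can underflow
its step size there when combined with a step cap, so the plain BDF
integrator is used (it agrees with an uncapped reference to 7 significant
digits on the affected parameter draws). States are floored at zero after
integration; an excursion below $-10^{-9}$ raises an error instead of
being silently clipped.

## Rejection ABC

`run_rejection()` draws parameters from log-uniform or point priors,
simulates the paired experiments for each draw, and accepts a draw when
its statistic falls within $k$ standard deviations of the observed mean —
for the per-strain mode, when that holds for *both* strains. Three shipped
presets (`abc_preset()`):

* **equal** — shared leakage $e$ over three decades ($10^{-2}$–10
  mmol/gDW); diffusion over one decade centred on the measured
  3.88e-5 L/h ($\log_{10}$ bounds −4.911 / −3.911); observed statistic
  1.14 (sd 0.235), $k = 2$.
* **unequal** — independent lysine and isoleucine leakage, $d$ fixed at
  3.88e-5 L/h; per-strain observed 0.925 (sd 0.015) and 1.35 (sd 0.026),
  $k = 10$.
* **noisy** — as *equal*, plus a one-decade log-uniform prior around every
  literature-estimated kinetic parameter (volumes stay fixed).

The observed means and standard deviations are *inputs* (they come from
the wet-lab experiments), not quantities the package recomputes. Every
draw is retained with its statistic and an accepted flag, so the prior,
the posterior and parameter-space maps of the statistic all come from one
run; simulation failures are recorded as rejected-with-error, never
dropped silently. Identical seeds reproduce the draw sequence and
acceptance set exactly.

Recovery behaviour, established by the test suite on synthetic observed
statistics: with a supercritical truth ($e = 1$) the posterior
concentrates within a fraction of a decade and its central 95% interval
contains the truth, though its median sits slightly *above* it — the
statistic peaks near $e = 1$, so draws just above the truth remain inside
the acceptance band while draws below fall out steeply. A vacuous
threshold ($k \to \infty$) returns the prior; with strongly unequal truths
($e_{lys} = 5$, $e_{ile} = 0.2$) the sign of $e_{lys} - e_{ile}$ is
recovered in 20/20 seeded repeats at $n = 300$ draws. Under the noisy
preset the leakage posterior remains clearly narrower than its prior: the
statistic constrains leakage even with order-of-magnitude uncertainty in
the kinetic constants.

## The synthetic-data generator

`gen_dye_experiment()`, `gen_amino_acid_sampling()` and
`gen_growth_experiment()` emulate the three bench protocols: 72-h/15-min
dye kinetics (three replicate pairs per pore size, 400 µM load against
water), destructive amino-acid sampling at 1.5/3/6/12/24 h with the
matching standard ladders (lysine 100…0 µM, isoleucine 1000…0 µM), and
96-h/15-min growth curves for any scenario. Concentrations map to OD
through a linear calibration (default slope 0.001 OD/µM, intercept
0.05 OD — placing the 400 µM load mid-scale) and noise is additive i.i.d.
Gaussian on OD (default sd 0.005), floored at zero: the minimal model
consistent with visibly smooth measured curves. Per-pore-size default
rates (0, 1e-5, 3.88e-5, 1e-4, 2.5e-4 L/h for none/0.03/0.1/0.2/0.4 µm)
rise monotonically with pore size and are anchored at the measured 0.1-µm
value; they are a plausible emulation, not measurements.

What the generator does *not* emulate — and what passing recovery tests
therefore cannot certify about real data: heteroscedastic or drifting
reader noise, evaporation, dye sequestration in the membrane (available
only as the optional `loss_rate` term), microbial crossover through or
around the membrane, lag phases, and death. Growth-curve shapes are the
model's own output, so growth tests demonstrate pipeline consistency, not
biological realism.

Every dataset carries a `synthetic_truth` record (all parameters plus the
seed); the same record reproduces byte-identical files.

## Problem sizes

The shipped tests and the acceptance script run the model at the sizes a
desk validation needs: 48-h horizons for statistic work, 100-replicate
Monte-Carlo batches for the noisy-fit calibration, 300–500 ABC draws per
posterior, and 20 seeded repeats for the directional-recovery check.
Larger runs only sharpen the Monte-Carlo estimates; the structure of the
results does not change.

## Known limitations

* The growth model is deliberately minimal — no genome-scale metabolism,
  maintenance, lag or death, no contact-dependent exchange — so inferred
  leakage values are conditional on that structure.
* The 48-h ratio statistic is non-monotone in leakage, so equal-leakage
  posteriors are asymmetric around a supercritical truth and
  uninformative below the cross-feeding threshold.
* Rejection ABC only: no sequential or regression-adjusted schemes.
* The diffusion estimator assumes a conserved tracer; with material loss
  it remains useful only as a per-side diagnostic of that loss.
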