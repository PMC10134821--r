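Package: coculture
Title: Modeling and Inference for Membrane-Separated Microbial Cocultures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying microbial interactions measured in
    transwell-style coculture plates, where pairs of wells exchange small
    molecules through a porous membrane. Provides plate-reader kinetic table
    handling (blank subtraction, linear calibration, experimental design
    arithmetic), a lumped two-compartment gradient-driven diffusion model with
    analytic solution and exponential rate estimation, a dynamic model of an
    obligate syntrophic pair of amino-acid auxotrophs with Michaelis-Menten
    uptake, minimum-flux (Liebig) Monod growth and growth-proportional
    leakage, rejection approximate Bayesian computation for leakage and
    diffusion parameters, and a synthetic-data generator that emulates
    plate-reader exports with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
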