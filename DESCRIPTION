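Package: microDMA
Title: Two-Probe Micromanipulation Bench for Viscoelasticity and
    Contractile-Force Screening of Fiber-Shaped Muscle Microtissues
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for two-probe cantilever
    micromanipulation of fiber-shaped skeletal-muscle microphysiological
    models. Provides an Euler-Bernoulli model of the sensing probe with
    pixel-quantized optical readout, constitutive models of hydrogel cores
    and cellular microbundles (Zener solid plus solution-drag loss, passive
    stiffening, twitch/tetanus active contraction), a physics-based synthetic
    bench that generates time-domain recordings of oscillatory stretching,
    length sweeps and electrical stimulation, a model-predictive force
    controller with a liquid-bridge force constraint, single-frequency
    spectral extraction of the complex modulus and loss factor together with
    Lissajous and contractile-force summaries, and a three-criterion
    screening engine (contractile force, loss factor, modulus increase) with
    funnel and dose-threshold procedures for large condition grids.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr,
    png
Config/testthat/edition: 3
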