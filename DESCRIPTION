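Package: rwdry
Title: Drying Kinetics, Energetics and Quality Analysis for Refractance
    Window Drying
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis chain for thin-layer refractance window (RW) drying
    experiments on leafy material: moisture-ratio kinetics and nonlinear
    fitting of six thin-layer drying models, effective moisture diffusivity
    from the Fick slab solution, Arrhenius activation energy,
    transition-state thermodynamics (enthalpy, entropy, Gibbs free energy),
    specific energy consumption with CO2/NOx emission accounting, CIELAB
    color and quality metrics, and a Levenberg-Marquardt-trained
    feedforward neural network for moisture-ratio prediction with topology
    search.  Includes a seeded synthetic-data generator that emulates a
    five-temperature RW drying experiment so the whole chain is testable
    without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
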