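Package: vsdtrack
Title: Simulating and Analysing Optical Tracking of Voltage-Sensor Gating Charges
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward simulation and analysis of voltage-clamp fluorimetry
    experiments that track a charged fluorophore (such as the bimane
    derivative qBBr) moving through the conformational trajectory of a
    voltage-sensing domain while being quenched by a nearby tryptophan.
    Provides continuous-time Markov models of voltage-sensor gating with
    voltage-dependent rates, a distance form of the Stern-Volmer quenching
    law, deterministic ensemble and stochastic single-molecule fluorescence
    observables, gating-current computation, a synthetic-recording generator
    emulating cut-open-oocyte acquisition (sampling, sweep averaging, noise,
    drift, photobleaching), and the standard trace-analysis pipeline:
    Bessel filtering, baseline subtraction, fractional fluorescence change,
    charge integration, exponential fitting, charge-voltage and
    fluorescence-voltage curves, Boltzmann fits, and Cole-Moore prepulse
    analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    signal,
    minpack.lm,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
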