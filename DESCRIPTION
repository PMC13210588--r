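Package: piezoneuron
Title: Deterministic and Stochastic Dynamics of a Piezoelectric Neuron Oscillator
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for a forced FitzHugh-Nagumo-type
    fast-slow oscillator describing a piezoelectric neuron circuit. Provides the
    deterministic forced model and its stochastic (additive Gaussian white noise)
    extension, adaptive deterministic integration and seed-controlled
    Euler-Maruyama ensembles, basin-of-attraction mapping, sensitivity to initial
    conditions, delay return maps, recurrence quantification analysis (recurrence
    rate, determinism, laminarity, diagonal-line entropy), ensemble statistics with
    confidence bands, final-time distribution fits, a coherence-resonance noise
    sweep, analytically tractable synthetic test signals, and a config-driven
    pipeline with plain-text (CSV/JSON/PGM) input and output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    grDevices,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
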